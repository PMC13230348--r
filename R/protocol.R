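#' Evaluation protocol configuration
#'
#' Bundles every tunable of a full evaluation run: which real split the
#' synthetic sample is compared against, whether the synthetic count is
#' matched to the real count or used at a fixed size, the extractor id, the
#' neighbour counts of the manifold metrics, the hypersphere quantile grid,
#' the kernel-distance settings, the authenticity target count, and the seed
#' that determines every stochastic step.
#'
#' @param real_source `"train"` or `"test"` (provenance label only).
#' @param n_synth `"matched"` (subsample synthetic to the real count, seeded,
#'   without replacement) or a fixed integer count.
#' @param extractor_id Identifier recorded in the report.
#' @param k_precision Neighbour count for precision/recall (default 3).
#' @param k_density Neighbour count for density/coverage (default 5).
#' @param grid Quantile grid for the hypersphere curves.
#' @param kid_cfg A [kernel_config()]; its seed is overridden by `seed`.
#' @param target_count Synthetic samples covered by the authenticity audit.
#' @param seed Integer master seed.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(real_source = "train", n_synth = "matched",
                        extractor_id = "precomputed", k_precision = 3L,
                        k_density = 5L, grid = default_grid(),
                        kid_cfg = kernel_config(), target_count = 50000L,
                        seed = 1L) {
  if (!identical(n_synth, "matched") && (!is.numeric(n_synth) || n_synth < 1)) {
    stop_data("n_synth must be 'matched' or a positive count")
  }
  structure(list(real_source = real_source, n_synth = n_synth,
                 extractor_id = extractor_id,
                 k_precision = as.integer(k_precision),
                 k_density = as.integer(k_density), grid = grid,
                 kid_cfg = kid_cfg, target_count = as.integer(target_count),
                 seed = as.integer(seed)),
            class = "eval_config")
}

metric_order <- list(
  composite = c("fid", "kid", "kid_sd"),
  fidelity = c("precision", "density", "alpha_precision"),
  diversity = c("recall", "coverage", "beta_recall"),
  generalization = c("authenticity"))

#' Run the full evaluation protocol
#'
#' Embeds the inputs if they are slice stacks, resolves the synthetic sample
#' size (matched mode subsamples to the real count, seeded, without
#' replacement), then computes the composite distribution metrics (Frechet
#' distance, kernel distance), the k-NN manifold metrics (precision, recall,
#' density, coverage) and the hypersphere one-class metrics (alpha-precision,
#' beta-recall, authenticity), grouped as fidelity / diversity /
#' generalization with the composite pair in its own joint subgroup. A
#' failing metric is recorded per-metric (value `NA`, message kept) and the
#' report is marked partial rather than aborting the run.
#'
#' @param real,synth `feature_matrix` objects or `slice_stack`s.
#' @param cfg An [eval_config()].
#' @param extractor Required when stacks are supplied.
#' @return Object of class `metric_report`.
#' @export
run_protocol <- function(real, synth, cfg = eval_config(), extractor = NULL) {
  stopifnot(inherits(cfg, "eval_config"))
  if (inherits(real, "slice_stack")) {
    if (is.null(extractor)) stop_data("an extractor is required for slice-stack input")
    real <- embed_stack(real, extractor, source = "real")
    cfg$extractor_id <- extractor$id
  }
  if (inherits(synth, "slice_stack")) {
    if (is.null(extractor)) stop_data("an extractor is required for slice-stack input")
    synth <- embed_stack(synth, extractor, source = "synthetic")
  }
  xr <- fm_values(real)
  xs <- fm_values(synth)
  if (ncol(xr) != ncol(xs)) stop_data("real and synthetic dimensions differ")

  n_target <- if (identical(cfg$n_synth, "matched")) nrow(xr) else as.integer(cfg$n_synth)
  if (n_target < nrow(xs)) {
    keep <- with_seed(cfg$seed, sample.int(nrow(xs), n_target))
    xs <- xs[keep, , drop = FALSE]
  }

  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }

  kid_cfg <- cfg$kid_cfg
  kid_cfg$seed <- cfg$seed
  kid_res <- grab("kid", kid(xs, xr, kid_cfg))
  real_m_p <- grab("precision", knn_radii(xr, cfg$k_precision))
  synth_m <- grab("recall", knn_radii(xs, cfg$k_precision))
  real_m_d <- grab("density", knn_radii(xr, cfg$k_density))
  oc <- grab("oc", fit_oc_transform(xr))
  hyp <- function(code) if (inherits(oc, "oc_model")) code else NA_real_
  real_h <- hyp(oc_map(xr, oc))
  synth_h <- hyp(oc_map(xs, oc))
  curve_val <- function(x) if (inherits(x, "quantile_curve")) x$auc_score else NA_real_

  scores <- list(
    composite = list(
      fid = grab("fid", frechet_distance(gaussian_moments(xr), gaussian_moments(xs))),
      kid = if (inherits(kid_res, "kid_result")) kid_res$mmd2 else NA_real_,
      kid_sd = if (inherits(kid_res, "kid_result")) kid_res$sd else NA_real_),
    fidelity = list(
      precision = grab("precision",
                       if (inherits(real_m_p, "manifold_model")) manifold_precision(real_m_p, xs) else NA_real_),
      density = grab("density",
                     if (inherits(real_m_d, "manifold_model")) manifold_density(real_m_d, xs) else NA_real_),
      alpha_precision = grab("alpha_precision",
                             curve_val(hyp(alpha_precision(real_h, synth_h, cfg$grid))))),
    diversity = list(
      recall = grab("recall",
                    if (inherits(synth_m, "manifold_model")) manifold_recall(xr, synth_m) else NA_real_),
      coverage = grab("coverage",
                      if (inherits(real_m_d, "manifold_model")) manifold_coverage(real_m_d, xs) else NA_real_),
      beta_recall = grab("beta_recall",
                         curve_val(hyp(beta_recall(real_h, synth_h, cfg$grid))))),
    generalization = list(
      authenticity = grab("authenticity",
                          authenticity(xr, xs, target_count = cfg$target_count,
                                       seed = cfg$seed, oc = if (inherits(oc, "oc_model")) oc else NULL)$final))
  )

  structure(list(
    scores = scores,
    n_real = nrow(xr), n_synth = nrow(xs),
    config = cfg, errors = errors, partial = length(errors) > 0,
    auc_rule = "1 - 2 * integral |curve - level| (trapezoid, anchored at 0)",
    meta = list(package = as.character(utils::packageVersion("synthmetrics")),
                r = R.version.string, timestamp = format(Sys.time(), tz = "UTC"))),
    class = "metric_report")
}

flatten_scores <- function(report) {
  rows <- do.call(rbind, lapply(names(metric_order), function(g) {
    data.frame(group = g, metric = metric_order[[g]],
               value = unlist(report$scores[[g]][metric_order[[g]]], use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: %d real vs %d synthetic (seed %d%s)\n",
              x$n_real, x$n_synth, x$config$seed,
              if (x$partial) ", PARTIAL" else ""))
  tab <- flatten_scores(x)
  for (g in unique(tab$group)) {
    cat(" ", g, "\n")
    sub <- tab[tab$group == g, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-16s %s\n", sub$metric[i],
                  formatC(sub$value[i], digits = 4, format = "fg")))
    }
  }
  invisible(x)
}

#' @export
summary.metric_report <- function(object, ...) {
  flatten_scores(object)
}

report_payload <- function(report) {
  cfg <- unclass(report$config)
  cfg$kid_cfg <- unclass(cfg$kid_cfg)
  list(scores = report$scores, n_real = report$n_real, n_synth = report$n_synth,
       config = cfg, errors = report$errors, partial = report$partial,
       auc_rule = report$auc_rule, meta = report$meta)
}

#' Write a metric report to disk
#'
#' JSON preserves the full grouped structure (round-trippable); CSV emits one
#' row per metric (`group,metric,value`) in a fixed deterministic order;
#' Markdown renders a grouped table with fidelity / diversity /
#' generalization headers.
#'
#' @param report A `metric_report`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "md")) {
  stopifnot(inherits(report, "metric_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (format == "csv") {
    utils::write.csv(flatten_scores(report), path, row.names = FALSE)
  } else {
    tab <- flatten_scores(report)
    lines <- c(sprintf("# Metric report (%d real vs %d synthetic, seed %d)",
                       report$n_real, report$n_synth, report$config$seed), "")
    for (g in unique(tab$group)) {
      lines <- c(lines, sprintf("## %s", g), "",
                 "| metric | value |", "| --- | --- |",
                 sprintf("| %s | %.6g |", tab$metric[tab$group == g],
                         tab$value[tab$group == g]), "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON metric report
#'
#' @param path JSON file written by [write_report()].
#' @return Nested list mirroring the report payload.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Persist a feature matrix as CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records source, extractor id and sample ids so
#' a reloaded matrix is fully traceable.
#'
#' @param features A `feature_matrix`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  utils::write.table(fm_values(features), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(source = attr(features, "source"),
                            extractor_id = attr(features, "extractor_id"),
                            sample_ids = attr(features, "sample_ids")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a feature matrix written by [write_features()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @param source Fallback source tag when there is no sidecar.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path, source = "real") {
  if (!file.exists(path)) stop_data("no such file: ", path)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    feature_matrix(vals, meta$source, meta$extractor_id, meta$sample_ids)
  } else {
    feature_matrix(vals, source)
  }
}

#' Rebuild a Turing session object from its answer key
#'
#' Allows scoring response files against a key CSV without the original
#' session object (e.g. from the command line).
#'
#' @param key data.frame with columns `item_id` and `label`.
#' @return A `turing_session` (presentation refs unavailable).
#' @export
session_from_key <- function(key) {
  if (!all(c("item_id", "label") %in% names(key))) {
    stop_data("key must have columns item_id and label")
  }
  structure(list(items = data.frame(item_id = key$item_id, ref = NA_character_),
                 key = key[, c("item_id", "label")],
                 n_real = sum(key$label == "real"),
                 n_synth = sum(key$label == "synthetic"), seed = NA_integer_),
            class = "turing_session")
}
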