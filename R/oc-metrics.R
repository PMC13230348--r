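# Nearest-rank quantile: the ceiling(p * n)-th order statistic.
quantile_nearest_rank <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  # small epsilon guards against ceiling(0.15 * 200) == 31 float artifacts
  xs[pmin(pmax(ceiling(p * n - 1e-9), 1L), n)]
}

#' Default quantile grid for the hypersphere curves
#'
#' 20 equally spaced levels 0.05, 0.10, ..., 1.00.
#' @return Numeric vector.
#' @export
default_grid <- function() seq(0.05, 1, by = 0.05)

quantile_curve <- function(grid, values) {
  if (length(grid) == 0L) stop_data("empty quantile grid")
  if (is.unsorted(grid, strictly = TRUE)) stop_data("grid must be strictly increasing")
  if (any(grid <= 0) || any(grid > 1)) stop_data("grid levels must lie in (0, 1]")
  # Deviation-from-diagonal AUC, normalized so perfect calibration scores 1
  # and maximal deviation 0: 1 - 2 * integral of |value - level|, trapezoid
  # over the grid anchored at (0, 0).
  g <- c(0, grid)
  dev <- c(0, abs(values - grid))
  integral <- sum(diff(g) * (utils::head(dev, -1) + utils::tail(dev, -1)) / 2)
  structure(list(grid = grid, values = values,
                 auc_score = min(max(1 - 2 * integral, 0), 1)),
            class = "quantile_curve")
}

#' @export
print.quantile_curve <- function(x, ...) {
  cat(sprintf("quantile_curve over %d levels: auc_score = %.4f\n",
              length(x$grid), x$auc_score))
  invisible(x)
}

#' Alpha-precision: outlier-robust fidelity on the hypersphere
#'
#' For each level `alpha` of the grid, `P(alpha)` is the fraction of synthetic
#' samples whose hypersphere radius is at most the `alpha`-quantile
#' (nearest-rank) of the real radii — i.e. the fraction of synthetic samples
#' falling inside the region where the `alpha` most typical real samples
#' live. A perfectly calibrated generator has `P(alpha) = alpha` at every
#' level; the summary score is `1 - 2 * integral |P(alpha) - alpha|`
#' (trapezoid over the grid), so 1 is ideal and 0 is maximal deviation.
#'
#' @param real_h,synth_h `hypersphere_embedding`s sharing the same fitted
#'   one-class model (see [oc_map()]).
#' @param grid Strictly increasing levels in (0, 1].
#' @return A `quantile_curve` with `auc_score` in \[0, 1\].
#' @export
alpha_precision <- function(real_h, synth_h, grid = default_grid()) {
  stopifnot(inherits(real_h, "hypersphere_embedding"),
            inherits(synth_h, "hypersphere_embedding"))
  q <- quantile_nearest_rank(real_h$radii, grid)
  values <- vapply(q, function(r) mean(synth_h$radii <= r), numeric(1))
  quantile_curve(grid, values)
}

#' Beta-recall: outlier-robust diversity on the hypersphere
#'
#' The mirror of [alpha_precision()] with real and synthetic roles swapped:
#' quantile thresholds come from the synthetic side and membership is counted
#' over real samples. The beta-support of the synthetic distribution is
#' anchored at the synthetic center (mean of the mapped synthetic samples):
#' a real sample is beta-covered when its nearest synthetic neighbour is
#' beta-typical (center distance at most the beta-quantile, nearest-rank, of
#' the nearest-neighbour center distances) and the real sample lies within
#' that neighbour's center-distance ball. `R(beta) = beta` for a perfect
#' generator; same deviation-AUC summary as alpha-precision.
#'
#' @inheritParams alpha_precision
#' @return A `quantile_curve` with `auc_score` in \[0, 1\].
#' @export
beta_recall <- function(real_h, synth_h, grid = default_grid()) {
  stopifnot(inherits(real_h, "hypersphere_embedding"),
            inherits(synth_h, "hypersphere_embedding"))
  synth_center <- colMeans(synth_h$mapped)
  center_d <- sqrt(rowSums(sweep(synth_h$mapped, 2, synth_center)^2))
  dmat <- cross_dist(real_h$mapped, synth_h$mapped)
  nn_idx <- apply(dmat, 1, which.min)
  nn_dist <- dmat[cbind(seq_len(nrow(dmat)), nn_idx)]
  nn_center_d <- center_d[nn_idx]
  inside_ball <- nn_dist <= nn_center_d
  q <- quantile_nearest_rank(nn_center_d, grid)
  values <- vapply(q, function(r) mean(inside_ball & nn_center_d <= r), numeric(1))
  quantile_curve(grid, values)
}

#' Flag memorized real samples against a synthetic batch
#'
#' A real sample is flagged as memorized when some synthetic sample lies
#' strictly closer to it than any other real sample does. The arg-min
#' synthetic sample of each flagged real is flagged as its memorizer. Both
#' matrices should be embedded by the same one-class transform (see
#' [authenticity()], which handles this).
#'
#' @param real,synth_batch Matrices (or `feature_matrix`s) with equal `d`.
#' @return List: `real_flags` (logical n_real), `synth_flags` (logical
#'   n_synth), `memorizer` (synthetic index of each real's nearest synthetic).
#' @export
flag_memorized <- function(real, synth_batch) {
  x <- fm_values(real)
  y <- fm_values(synth_batch)
  if (ncol(x) != ncol(y)) stop_data("dimension mismatch between real and synthetic")
  if (nrow(x) < 2L) stop_data("need at least 2 real samples")
  drr <- cross_dist(x, x)
  diag(drr) <- Inf
  rr <- apply(drr, 1, min)
  drs <- cross_dist(x, y)
  nn_idx <- apply(drs, 1, which.min)
  rs <- drs[cbind(seq_len(nrow(x)), nn_idx)]
  real_flags <- rs < rr
  synth_flags <- rep(FALSE, nrow(y))
  synth_flags[unique(nn_idx[real_flags])] <- TRUE
  list(real_flags = real_flags, synth_flags = synth_flags, memorizer = nn_idx)
}

#' Authenticity: fraction of synthetic samples not memorized
#'
#' Real and synthetic features are embedded with the one-class transform
#' fitted on the reals, then the synthetic samples are partitioned (by a
#' seeded permutation) into disjoint batches of the real-sample size, until
#' `target_count` synthetic samples are covered (capped at the available
#' count; the final partial batch is included and weighted by its own size).
#' Each batch is audited with [flag_memorized()]; the batch score is
#' `1 - (#flagged synthetic) / (batch size)`, deduplicating synthetic samples
#' that memorize several reals, and the final value is the size-weighted mean
#' over batches. 1 means fully novel synthetic data; 0 means every synthetic
#' sample shadows a real one.
#'
#' @param real,synth `feature_matrix` objects (or matrices) with equal `d`.
#' @param target_count Number of synthetic samples to cover (default 50000).
#' @param seed Seed for the batch partition.
#' @param oc Optional prefitted `oc_model`; fitted on `real` when `NULL`.
#' @return Object of class `authenticity_result`: `per_batch_scores`,
#'   `batch_sizes`, `batch_size`, `n_batches`, `final`.
#' @export
authenticity <- function(real, synth, target_count = 50000L, seed = 1L, oc = NULL) {
  if (is.null(oc)) oc <- fit_oc_transform(real)
  xr <- oc_map(real, oc)$mapped
  xs <- oc_map(synth, oc)$mapped
  n_real <- nrow(xr)
  n_synth <- nrow(xs)
  if (n_synth < n_real) {
    warning("fewer synthetic than real samples; auditing a single undersized batch")
    batches <- list(seq_len(n_synth))
  } else {
    n_use <- min(target_count, n_synth)
    perm <- with_seed(seed, sample.int(n_synth))[seq_len(n_use)]
    starts <- seq(1L, n_use, by = n_real)
    batches <- lapply(starts, function(s) perm[s:min(s + n_real - 1L, n_use)])
  }
  sizes <- lengths(batches)
  flagged <- vapply(batches, function(idx) {
    sum(flag_memorized(xr, xs[idx, , drop = FALSE])$synth_flags)
  }, numeric(1))
  scores <- 1 - flagged / sizes
  structure(list(per_batch_scores = scores, batch_sizes = sizes,
                 batch_size = n_real, n_batches = length(batches),
                 final = 1 - sum(flagged) / sum(sizes)),
            class = "authenticity_result")
}

#' @export
print.authenticity_result <- function(x, ...) {
  cat(sprintf("authenticity: %.4f over %d batch(es) of nominal size %d\n",
              x$final, x$n_batches, x$batch_size))
  invisible(x)
}
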