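#' Build a blinded visual Turing-test session
#'
#' Samples `n_each` real and `n_each` synthetic image references without
#' replacement and shuffles them into a seeded random presentation order.
#' The presentation list carries no labels; the answer key is a separate
#' table, so the session can be administered blinded.
#'
#' @param real_refs,synth_refs Character vectors of image references (paths
#'   or ids) to sample from.
#' @param n_each Images per class (default 50, i.e. a 100-image session).
#' @param seed Seed for sampling and shuffling.
#' @return Object of class `turing_session`: `items` (data.frame
#'   `item_id`, `ref`), `key` (data.frame `item_id`, `label`), `n_real`,
#'   `n_synth`, `seed`.
#' @export
build_session <- function(real_refs, synth_refs, n_each = 50L, seed = 1L) {
  n_each <- as.integer(n_each)
  if (length(real_refs) < n_each) {
    stop_data("only ", length(real_refs), " real references for n_each = ", n_each)
  }
  if (length(synth_refs) < n_each) {
    stop_data("only ", length(synth_refs), " synthetic references for n_each = ", n_each)
  }
  with_seed(seed, {
    reals <- sample(real_refs, n_each)
    synths <- sample(synth_refs, n_each)
    refs <- c(reals, synths)
    labels <- rep(c("real", "synthetic"), each = n_each)
    ord <- sample.int(2L * n_each)
    structure(list(
      items = data.frame(item_id = seq_len(2L * n_each), ref = refs[ord],
                         stringsAsFactors = FALSE),
      key = data.frame(item_id = seq_len(2L * n_each), label = labels[ord],
                       stringsAsFactors = FALSE),
      n_real = n_each, n_synth = n_each, seed = seed),
      class = "turing_session")
  })
}

#' Construct confusion counts
#'
#' `TP` = real called real, `FN` = real called synthetic, `TN` = synthetic
#' called synthetic, `FP` = synthetic called real.
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_data("counts must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Score observer responses against a Turing session's answer key
#'
#' @param session A `turing_session`.
#' @param responses data.frame with columns `item_id` and `label`
#'   (`"real"`/`"synthetic"`), one row per session item.
#' @return A `confusion_counts`.
#' @export
score_responses <- function(session, responses) {
  stopifnot(inherits(session, "turing_session"))
  key <- session$key
  if (!all(c("item_id", "label") %in% names(responses))) {
    stop_data("responses must have columns item_id and label")
  }
  missing_ids <- setdiff(key$item_id, responses$item_id)
  extra_ids <- setdiff(responses$item_id, key$item_id)
  if (length(missing_ids) || length(extra_ids) || anyDuplicated(responses$item_id)) {
    stop_data("response/item mismatch; missing: [",
              paste(missing_ids, collapse = ","), "], extra/duplicated: [",
              paste(c(extra_ids, responses$item_id[duplicated(responses$item_id)]),
                    collapse = ","), "]")
  }
  if (!all(responses$label %in% c("real", "synthetic"))) {
    stop_data("labels must be 'real' or 'synthetic'")
  }
  resp <- responses$label[match(key$item_id, responses$item_id)]
  truth <- key$label
  confusion_counts(
    TP = sum(truth == "real" & resp == "real"),
    FP = sum(truth == "synthetic" & resp == "real"),
    TN = sum(truth == "synthetic" & resp == "synthetic"),
    FN = sum(truth == "real" & resp == "synthetic"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)` (real
#' images detected as real), `specificity = TN/(TN+FP)` (synthetic images
#' detected as synthetic). Values are returned at full precision together
#' with 2-decimal half-up-rounded versions as conventionally printed; a zero
#' denominator yields `NA` for that metric.
#'
#' @param c A `confusion_counts`.
#' @return List with `accuracy`, `sensitivity`, `specificity`, and `rounded`
#'   (the same three at 2 decimals).
#' @examples
#' confusion_metrics(confusion_counts(TP = 36, FP = 33, TN = 17, FN = 14))
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  acc <- if (total > 0) (c$TP + c$TN) / total else NA_real_
  sens <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  spec <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       rounded = list(accuracy = round_half_up(acc),
                      sensitivity = round_half_up(sens),
                      specificity = round_half_up(spec)))
}

#' Cosine k-nearest synthetic neighbours of each real embedding
#'
#' For each real sample, the `k` synthetic samples with the largest cosine
#' similarity, ranked; ties broken by smaller synthetic index. The standard
#' memorization visualization pairs each real image with its closest
#' synthetic counterparts.
#'
#' @param real_f,synth_f `feature_matrix` objects (or matrices) of equal `d`
#'   with no zero-norm rows.
#' @param k Neighbours per real sample (default 4).
#' @return Object of class `neighbor_table`: `indices` (n_real x k),
#'   `similarities` (n_real x k, non-increasing within rows), `k`.
#' @export
cosine_neighbors <- function(real_f, synth_f, k = 4L) {
  x <- fm_values(real_f)
  y <- fm_values(synth_f)
  if (ncol(x) != ncol(y)) stop_data("dimension mismatch")
  k <- as.integer(k)
  if (k < 1L || k > nrow(y)) stop_data("k must be in [1, number of synthetic samples]")
  nx <- sqrt(rowSums(x^2))
  ny <- sqrt(rowSums(y^2))
  if (any(nx == 0)) stop_data("zero-norm real vector at index ", which(nx == 0)[1L])
  if (any(ny == 0)) stop_data("zero-norm synthetic vector at index ", which(ny == 0)[1L])
  sim <- tcrossprod(x / nx, y / ny)
  sim <- pmin(pmax(sim, -1), 1)
  idx <- t(apply(sim, 1, function(row) order(-row, seq_along(row))[seq_len(k)]))
  if (k == 1L) idx <- matrix(idx, ncol = 1L)
  sims <- matrix(sim[cbind(rep(seq_len(nrow(x)), each = k), as.vector(t(idx)))],
                 ncol = k, byrow = TRUE)
  structure(list(indices = idx, similarities = sims, k = k),
            class = "neighbor_table")
}

#' Select the top-matching real rows of a neighbour table for display
#'
#' Picks the `n_real_shown` real samples with the largest rank-1 cosine
#' similarity to any synthetic sample (ties broken by smaller real index) and
#' emits an ordered montage layout, one row per selected real: the real image
#' followed by its `k` ranked synthetic neighbours.
#'
#' @param table A `neighbor_table`.
#' @param n_real_shown Number of real rows to display (default 2).
#' @return List of class `montage_spec`: `real_indices`, `rows` (list of
#'   integer vectors `c(real, neighbours...)` as synthetic indices), `n_rows`,
#'   `n_cols` (`1 + k`).
#' @export
top_matches <- function(table, n_real_shown = 2L) {
  stopifnot(inherits(table, "neighbor_table"))
  n_real_shown <- min(as.integer(n_real_shown), nrow(table$indices))
  top_sim <- table$similarities[, 1L]
  sel <- order(-top_sim, seq_along(top_sim))[seq_len(n_real_shown)]
  rows <- lapply(sel, function(i) c(real = i, table$indices[i, ]))
  structure(list(real_indices = sel, rows = rows,
                 n_rows = n_real_shown, n_cols = 1L + table$k),
            class = "montage_spec")
}

#' Write a Turing session to CSV files (presentation + separate answer key)
#'
#' @param session A `turing_session`.
#' @param items_path,key_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_session <- function(session, items_path, key_path) {
  stopifnot(inherits(session, "turing_session"))
  utils::write.csv(session$items, items_path, row.names = FALSE)
  utils::write.csv(session$key, key_path, row.names = FALSE)
  invisible(c(items_path, key_path))
}

#' Read observer responses from CSV
#'
#' @param path CSV with columns `item_id,label`.
#' @return data.frame suitable for [score_responses()].
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
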