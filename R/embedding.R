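#' Construct a feature matrix
#'
#' All metrics operate on n x d embeddings tagged with their source
#' (real or synthetic) and the extractor that produced them.
#'
#' @param values Numeric n x d matrix, rows = samples.
#' @param source `"real"` or `"synthetic"`.
#' @param extractor_id Identifier of the feature extractor used.
#' @param sample_ids Optional per-row identifiers.
#' @return Numeric matrix of class `feature_matrix` with `source`,
#'   `extractor_id` and `sample_ids` attributes.
#' @export
feature_matrix <- function(values, source = c("real", "synthetic"),
                           extractor_id = "unknown", sample_ids = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) stop_data("feature matrix must be at least 1 x 1")
  if (any(!is.finite(values))) {
    bad <- which(rowSums(!is.finite(values)) > 0)[1L]
    stop_data("non-finite feature values (first offending row: ", bad, ")")
  }
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(values))
  structure(values, class = c("feature_matrix", class(values)),
            source = source, extractor_id = extractor_id, sample_ids = sample_ids)
}

# Strip class/attributes down to a plain numeric matrix.
fm_values <- function(x) {
  m <- as.matrix(unclass(x))
  attr(m, "source") <- NULL
  attr(m, "extractor_id") <- NULL
  attr(m, "sample_ids") <- NULL
  m
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d x %d [%s, extractor '%s']\n",
              nrow(x), ncol(x), attr(x, "source"), attr(x, "extractor_id")))
  invisible(x)
}

#' Flattening (identity) feature extractor
#'
#' Maps an H x W image to its H*W pixel vector (column-major). Useful for
#' exercising the full image-to-metric path without pretrained weights.
#'
#' @return An extractor: a list with `id` and `fn(image) -> numeric vector`.
#' @export
extractor_flatten <- function() {
  list(id = "flatten", fn = function(image) as.numeric(image))
}

#' Seeded random-projection feature extractor
#'
#' Projects the flattened image onto `out_dim` fixed Gaussian directions
#' (scaled by `1/sqrt(in_dim)`). The projection matrix is drawn once from the
#' seed, so the extractor is deterministic across calls and sessions.
#'
#' @param in_dim Input dimension (H*W of the images it will see).
#' @param out_dim Output embedding dimension.
#' @param seed Integer seed for the projection matrix.
#' @return An extractor list with `id` and `fn`.
#' @export
extractor_random_projection <- function(in_dim, out_dim = 64L, seed = 1L) {
  proj <- with_seed(seed, matrix(stats::rnorm(in_dim * out_dim), in_dim, out_dim)) /
    sqrt(in_dim)
  list(id = sprintf("randproj-%d-%d-seed%d", in_dim, out_dim, as.integer(seed)),
       fn = function(image) {
         v <- as.numeric(image)
         if (length(v) != nrow(proj)) stop_data("extractor input dim ", length(v),
                                                " != expected ", nrow(proj))
         as.numeric(crossprod(proj, v))
       })
}

#' Embed a slice stack with a feature extractor
#'
#' Row i of the result is `extractor$fn(image i)`; the extractor id is
#' recorded so that every downstream score is traceable to the embedding
#' that produced it.
#'
#' @param stack A `slice_stack`.
#' @param extractor An extractor (see [extractor_flatten()]).
#' @param source `"real"` or `"synthetic"` tag for the resulting matrix.
#' @return A `feature_matrix` with `n = N` rows.
#' @export
embed_stack <- function(stack, extractor, source = "real") {
  stopifnot(inherits(stack, "slice_stack"))
  n <- n_slices(stack)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- extractor$fn(stack$images[, , i])
    if (any(!is.finite(v))) stop_data("extractor returned non-finite values at image ", i)
    rows[[i]] <- v
  }
  feature_matrix(do.call(rbind, rows), source = source, extractor_id = extractor$id)
}

#' Fit the one-class hypersphere transform on real embeddings
#'
#' Deterministic whitening transform standing behind the one-class-classifier
#' contract of the hypersphere metrics: the real mean becomes the hypersphere
#' center and each sample's radius is its ridge-regularized Mahalanobis
#' distance from that center, so typical samples sit near the center and
#' outliers near the boundary. Radii are invariant to rigid rotations of the
#' input features.
#'
#' @param real A `feature_matrix` (or plain matrix) of real embeddings,
#'   `n >= 2`.
#' @param ridge Relative ridge added to the covariance,
#'   `epsilon = ridge * trace(Sigma) / d`. Default `1e-6`.
#' @return Object of class `oc_model`: center, whitening matrix, and the
#'   radii of the fitting set.
#' @export
fit_oc_transform <- function(real, ridge = 1e-6) {
  x <- fm_values(real)
  if (nrow(x) < 2L) stop_data("need at least 2 samples to fit the one-class transform")
  center <- colMeans(x)
  sigma <- stats::cov(x)
  d <- ncol(x)
  eg <- eigen(sigma, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-10
  if (any(eg$values <= tol)) {
    warning("rank-deficient covariance; using ridge-regularized whitening")
  }
  eps <- ridge * sum(diag(sigma)) / d
  if (eps <= 0) {
    # Degenerate fitting set (zero total variance): identity mapping, radii 0.
    W <- diag(d)
  } else {
    W <- eg$vectors %*% diag(1 / sqrt(eg$values + eps), d) %*% t(eg$vectors)
  }
  model <- structure(list(center = center, W = W, d = d, ridge = ridge),
                     class = "oc_model")
  model$train_radii <- oc_map(real, model)$radii
  model
}

#' Map features into the fitted hypersphere
#'
#' Applies the whitening transform of an `oc_model`; the hypersphere center
#' maps to the origin and each sample's radius is its Euclidean norm in the
#' mapped space. Reapplying to the fitting set reproduces the radii stored at
#' fit time exactly.
#'
#' @param features A `feature_matrix` or matrix with `d` matching the model.
#' @param model An `oc_model` from [fit_oc_transform()].
#' @return Object of class `hypersphere_embedding`: `mapped` (n x d),
#'   `center` (origin in mapped coordinates) and `radii`.
#' @export
oc_map <- function(features, model) {
  stopifnot(inherits(model, "oc_model"))
  x <- fm_values(features)
  if (ncol(x) != model$d) {
    stop_data("feature dimension ", ncol(x), " does not match model dimension ", model$d)
  }
  mapped <- sweep(x, 2, model$center) %*% model$W
  structure(list(mapped = mapped,
                 center = rep(0, model$d),
                 radii = sqrt(rowSums(mapped^2))),
            class = "hypersphere_embedding")
}

#' @export
print.oc_model <- function(x, ...) {
  cat(sprintf("oc_model: d = %d, ridge = %g, fitted on %d samples (mean radius %.3f)\n",
              x$d, x$ridge, length(x$train_radii), mean(x$train_radii)))
  invisible(x)
}
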