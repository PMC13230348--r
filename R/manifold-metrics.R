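#' k-nearest-neighbour manifold model of an embedded sample
#'
#' The support of a distribution is estimated as the union of Euclidean
#' spheres centered at the embedded samples, each with radius equal to the
#' distance from that sample to its k-th nearest other sample (self excluded;
#' neighbour ties broken by smaller index).
#'
#' @param features A `feature_matrix` or matrix, `n > k`.
#' @param k Neighbour count, `>= 1`.
#' @return Object of class `manifold_model`: `points`, `k`, `radii`.
#' @examples
#' m <- knn_radii(matrix(c(0, 1, 3), 3, 1), k = 1)
#' m$radii  # 1 1 2
#' @export
knn_radii <- function(features, k = 3L) {
  x <- fm_values(features)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L) stop_data("k must be >= 1")
  if (n <= k) stop_data("need n > k (n = ", n, ", k = ", k, ")")
  dmat <- cross_dist(x, x)
  diag(dmat) <- Inf
  radii <- apply(dmat, 1, function(row) sort(row, method = "radix")[k])
  structure(list(points = x, k = k, radii = radii), class = "manifold_model")
}

# Membership counts of query points in the model's spheres:
# counts[j] = number of model spheres containing query j;
# covered[i] = TRUE if model sphere i contains at least one query point.
sphere_membership <- function(model, query) {
  q <- fm_values(query)
  dmat <- cross_dist(model$points, q)      # n_model x n_query
  inside <- dmat <= model$radii            # radii recycled down columns
  list(counts = colSums(inside), covered = rowSums(inside) > 0)
}

#' Manifold precision: fidelity of synthetic samples
#'
#' Fraction of synthetic samples that fall inside the estimated real-data
#' manifold (within the k-NN sphere of at least one real sample).
#'
#' @param real_m A `manifold_model` built on real embeddings.
#' @param synth Synthetic `feature_matrix`.
#' @return Score in \[0, 1\]; 1 is ideal.
#' @export
manifold_precision <- function(real_m, synth) {
  stopifnot(inherits(real_m, "manifold_model"))
  mean(sphere_membership(real_m, synth)$counts > 0)
}

#' Manifold recall: diversity of synthetic samples
#'
#' Fraction of real samples covered by the synthetic-data manifold — the
#' mirror image of [manifold_precision()] with the roles of the two samples
#' swapped.
#'
#' @param real Real `feature_matrix`.
#' @param synth_m A `manifold_model` built on synthetic embeddings.
#' @return Score in \[0, 1\]; 1 is ideal.
#' @export
manifold_recall <- function(real, synth_m) {
  stopifnot(inherits(synth_m, "manifold_model"))
  mean(sphere_membership(synth_m, real)$counts > 0)
}

#' Manifold density: outlier-robust fidelity
#'
#' `1/(k M)` times the total number of (real sphere, synthetic sample)
#' containments, `M` the synthetic count. Unlike precision, a single huge
#' outlier sphere contributes at most one containment per synthetic sample,
#' so density is not inflated by real outliers. May exceed 1.
#'
#' @inheritParams manifold_precision
#' @return Nonnegative score; around 1 when synthetic matches real.
#' @export
manifold_density <- function(real_m, synth) {
  stopifnot(inherits(real_m, "manifold_model"))
  counts <- sphere_membership(real_m, synth)$counts
  sum(counts) / (real_m$k * length(counts))
}

#' Manifold coverage: outlier-robust diversity
#'
#' Fraction of real samples whose k-NN sphere contains at least one synthetic
#' sample. The manifold is built around the real data, so dropped modes show
#' up as uncovered real spheres.
#'
#' @inheritParams manifold_precision
#' @return Score in \[0, 1\]; 1 is ideal.
#' @export
manifold_coverage <- function(real_m, synth) {
  stopifnot(inherits(real_m, "manifold_model"))
  mean(sphere_membership(real_m, synth)$covered)
}

#' @export
print.manifold_model <- function(x, ...) {
  cat(sprintf("manifold_model: %d points in %d-d, k = %d, radii in [%.3g, %.3g]\n",
              nrow(x$points), ncol(x$points), x$k, min(x$radii), max(x$radii)))
  invisible(x)
}
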