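#' Gaussian moments of an embedded sample
#'
#' Sample mean and sample covariance (divisor n - 1) of a feature matrix:
#' the Gaussian approximation under which the Frechet distance between real
#' and synthetic embedding distributions is computed.
#'
#' @param features A `feature_matrix` or numeric matrix, `n >= 2`.
#' @return Object of class `gaussian_moments` with `mean`, `covariance`, `n`.
#' @export
gaussian_moments <- function(features) {
  x <- fm_values(features)
  if (nrow(x) < 2L) stop_data("need at least 2 samples to estimate moments")
  structure(list(mean = colMeans(x), covariance = stats::cov(x), n = nrow(x)),
            class = "gaussian_moments")
}

# Validate symmetry and (near-)PSD-ness; returns the symmetrized matrix.
check_psd <- function(sigma, tol = 1e-6, label = "covariance") {
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma)))) {
    stop_numeric(label, " is not symmetric within tolerance")
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tol * scale) {
    stop_numeric(label, " has negative eigenvalue ", signif(min(ev), 4),
                 " beyond tolerance")
  }
  sigma
}

# Symmetric PSD square root via eigendecomposition, clipping tiny negatives.
sqrtm_psd <- function(sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(sigma)) %*% t(eg$vectors)
}

#' Frechet (Wasserstein-2) distance between two Gaussians
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, the quantity
#' behind FID when the moments come from Inception-style embeddings. The
#' cross-term square root is computed via the symmetric eigendecomposition of
#' `S_a^{1/2} S_b S_a^{1/2}`; eigenvalues below `-1e-6` (relative) raise an
#' error, smaller negatives are clipped to zero, and a slightly negative
#' total trace term is clipped so the result is nonnegative.
#'
#' @param a,b `gaussian_moments` of equal dimension.
#' @return Nonnegative scalar; 0 iff the moments are equal (within tolerance).
#' @examples
#' m1 <- gaussian_moments(matrix(rnorm(200), 100, 2))
#' frechet_distance(m1, m1)  # 0
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "gaussian_moments"), inherits(b, "gaussian_moments"))
  if (length(a$mean) != length(b$mean)) stop_data("dimension mismatch between moment sets")
  sa <- check_psd(a$covariance, label = "covariance of a")
  sb <- check_psd(b$covariance, label = "covariance of b")
  dmu <- a$mean - b$mean
  sa_half <- sqrtm_psd(sa)
  inner <- sa_half %*% sb %*% sa_half
  ev <- eigen((inner + t(inner)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-6 * scale) {
    stop_numeric("cross-covariance term has eigenvalue ", signif(min(ev), 4),
                 " beyond tolerance")
  }
  tr_cross <- sum(sqrt(pmax(ev, 0)))
  val <- sum(dmu^2) + sum(diag(sa)) + sum(diag(sb)) - 2 * tr_cross
  max(val, 0)
}

#' Kernel configuration for the kernel distance
#'
#' Polynomial kernel `k(u, v) = (u'v * scale + offset)^degree` with the
#' standard cubic default (`degree = 3`, `scale = 1/d`, `offset = 1`), and
#' the subset-averaging scheme of the unbiased MMD^2 estimator.
#'
#' @param degree Polynomial degree, `>= 1`.
#' @param scale Inner-product scale; `NULL` means `1/d` at evaluation time.
#' @param offset Kernel offset.
#' @param subset_size Samples per subset (`m`); `NULL` means
#'   `min(nx, ny, 1000)`.
#' @param n_subsets Number of random subsets averaged.
#' @param seed Seed for subset sampling.
#' @return Object of class `kernel_config`.
#' @export
kernel_config <- function(degree = 3L, scale = NULL, offset = 1,
                          subset_size = NULL, n_subsets = 100L, seed = 1L) {
  if (degree < 1L) stop_data("kernel degree must be >= 1")
  if (!is.null(subset_size) && subset_size < 2L) stop_data("subset_size must be >= 2")
  structure(list(degree = as.integer(degree), scale = scale, offset = offset,
                 subset_size = subset_size, n_subsets = as.integer(n_subsets),
                 seed = seed),
            class = "kernel_config")
}

poly_kernel <- function(x, y, degree, scale, offset) {
  (tcrossprod(x, y) * scale + offset)^degree
}

# Unbiased MMD^2 between two equal-size samples under a precomputed kernel.
mmd2_unbiased <- function(kxx, kyy, kxy) {
  m <- nrow(kxx)
  n <- nrow(kyy)
  (sum(kxx) - sum(diag(kxx))) / (m * (m - 1)) +
    (sum(kyy) - sum(diag(kyy))) / (n * (n - 1)) -
    2 * mean(kxy)
}

#' Kernel distance (polynomial-kernel MMD^2) between two embedded samples
#'
#' The unbiased squared maximum mean discrepancy under a polynomial kernel,
#' averaged over `n_subsets` seeded random subsets of `subset_size` rows from
#' each sample (sampled without replacement within a subset). Reports the
#' mean — the KID score — and the standard deviation across subsets.
#'
#' @param x,y `feature_matrix` objects (or matrices) with equal `d`.
#' @param cfg A [kernel_config()].
#' @return List of class `kid_result`: `mmd2` (mean), `sd`, `n_subsets`,
#'   `subset_size`.
#' @export
kid <- function(x, y, cfg = kernel_config()) {
  xv <- fm_values(x)
  yv <- fm_values(y)
  if (ncol(xv) != ncol(yv)) stop_data("dimension mismatch between x and y")
  d <- ncol(xv)
  scale <- if (is.null(cfg$scale)) 1 / d else cfg$scale
  m <- if (is.null(cfg$subset_size)) min(nrow(xv), nrow(yv), 1000L) else cfg$subset_size
  if (m > min(nrow(xv), nrow(yv))) {
    stop_data("subset_size ", m, " exceeds available samples (",
              min(nrow(xv), nrow(yv)), ")")
  }
  vals <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_subsets), function(s) {
      xi <- xv[sample.int(nrow(xv), m), , drop = FALSE]
      yi <- yv[sample.int(nrow(yv), m), , drop = FALSE]
      mmd2_unbiased(poly_kernel(xi, xi, cfg$degree, scale, cfg$offset),
                    poly_kernel(yi, yi, cfg$degree, scale, cfg$offset),
                    poly_kernel(xi, yi, cfg$degree, scale, cfg$offset))
    }, numeric(1))
  })
  structure(list(mmd2 = mean(vals), sd = stats::sd(vals),
                 n_subsets = cfg$n_subsets, subset_size = m),
            class = "kid_result")
}

#' @export
print.kid_result <- function(x, ...) {
  cat(sprintf("KID: %.6g (sd %.3g over %d subsets of %d)\n",
              x$mmd2, x$sd, x$n_subsets, x$subset_size))
  invisible(x)
}
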