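#' Scenario specification for synthetic real/synthetic feature clouds
#'
#' Describes a Gaussian-mixture "real" distribution together with the
#' generator pathologies the synthetic cloud should exhibit: a global mean
#' shift (fidelity degradation), dropped modes (diversity collapse), and a
#' fraction of jittered copies of real samples (memorization). The default is
#' two well-separated spherical modes (centers 8 sd apart, so brute-force
#' geometric expectations are exact to high probability) and no pathology.
#'
#' @param n_real,n_synth Sample counts.
#' @param d Embedding dimension.
#' @param modes List of mixture components, each `list(mean, sd, weight)`;
#'   weights must sum to 1. `mean` is recycled to length `d`.
#' @param shift Global mean offset added to synthetic samples (recycled to
#'   length `d`).
#' @param mode_drop Integer indices of modes absent from the synthetic cloud.
#' @param copy_frac Fraction in \[0, 1\] of synthetic samples replaced by
#'   jittered copies of real samples.
#' @param jitter_sd Standard deviation of the copy jitter, `>= 0`.
#' @param seed Integer seed; the output is fully determined by it.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_real = 400L, n_synth = 400L, d = 4L,
                          modes = list(list(mean = 4, sd = 1, weight = 0.5),
                                       list(mean = -4, sd = 1, weight = 0.5)),
                          shift = 0, mode_drop = integer(0), copy_frac = 0,
                          jitter_sd = 0, seed = 1L) {
  w <- vapply(modes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop_data("mode weights must sum to 1")
  if (copy_frac < 0 || copy_frac > 1) stop_data("copy_frac must be in [0, 1]")
  if (jitter_sd < 0) stop_data("jitter_sd must be >= 0")
  if (length(mode_drop) >= length(modes)) stop_data("cannot drop every mode")
  structure(list(n_real = as.integer(n_real), n_synth = as.integer(n_synth),
                 d = as.integer(d), modes = modes, shift = shift,
                 mode_drop = as.integer(mode_drop), copy_frac = copy_frac,
                 jitter_sd = jitter_sd, seed = seed),
            class = "scenario_spec")
}

draw_mixture <- function(n, d, modes, weights) {
  assign <- sample.int(length(modes), n, replace = TRUE, prob = weights)
  x <- matrix(stats::rnorm(n * d), n, d)
  for (m in seq_along(modes)) {
    rows <- assign == m
    if (!any(rows)) next
    mu <- rep_len(modes[[m]]$mean, d)
    x[rows, ] <- x[rows, , drop = FALSE] * modes[[m]]$sd +
      matrix(mu, sum(rows), d, byrow = TRUE)
  }
  list(x = x, assign = assign)
}

#' Generate paired real and synthetic feature clouds from a scenario
#'
#' The real cloud is drawn from the full mixture; the synthetic cloud from
#' the surviving (non-dropped) modes with renormalized weights, then shifted,
#' and finally a `copy_frac` fraction of its rows is replaced by uniformly
#' sampled real rows plus isotropic `N(0, jitter_sd^2)` noise. Everything is
#' determined by `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @return List with `real` and `synth` `feature_matrix` objects and the
#'   per-sample mixture assignments (`real_modes`, `synth_modes`;
#'   copies get assignment `NA`).
#' @export
gen_feature_clouds <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  keep <- setdiff(seq_along(spec$modes), spec$mode_drop)
  if (length(keep) == 0L) stop_data("empty surviving synthetic mixture")
  w <- vapply(spec$modes, `[[`, numeric(1), "weight")
  with_seed(spec$seed, {
    real <- draw_mixture(spec$n_real, spec$d, spec$modes, w)
    synth <- draw_mixture(spec$n_synth, spec$d, spec$modes[keep], w[keep] / sum(w[keep]))
    synth_modes <- keep[synth$assign]
    xs <- synth$x + matrix(rep_len(spec$shift, spec$d), spec$n_synth, spec$d, byrow = TRUE)
    n_copy <- floor(spec$copy_frac * spec$n_synth)
    if (n_copy > 0L) {
      src <- sample.int(spec$n_real, n_copy, replace = n_copy > spec$n_real)
      rows <- seq_len(n_copy)
      xs[rows, ] <- real$x[src, , drop = FALSE] +
        matrix(stats::rnorm(n_copy * spec$d, sd = spec$jitter_sd), n_copy, spec$d)
      synth_modes[rows] <- NA_integer_
    }
    list(real = feature_matrix(real$x, "real", "scenario"),
         synth = feature_matrix(xs, "synthetic", "scenario"),
         real_modes = real$assign, synth_modes = synth_modes)
  })
}

#' Generate a phantom brain-slice stack
#'
#' `n` grayscale images of a centered ellipse with seeded randomized axes,
#' a vertical intensity gradient and multiplicative speckle texture — a toy
#' stand-in for 2D brain slices that exercises the image-to-embedding-to-
#' metric path. Intensities are quantized to a 1/256 grid, so 32-bit NIfTI
#' round-trips are bit-exact.
#'
#' @param n Number of images, `>= 1`.
#' @param size Square image side in pixels.
#' @param seed Integer seed; same seed gives a bit-identical stack.
#' @return A `slice_stack` of `n` `size` x `size` images in \[0, 1\].
#' @export
gen_phantom_stack <- function(n, size = 64L, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop_data("n must be >= 1")
  size <- as.integer(size)
  cx <- (size + 1) / 2
  coords <- expand.grid(x = seq_len(size), y = seq_len(size))
  with_seed(seed, {
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      ax <- stats::runif(1, 0.25, 0.45) * size
      ay <- stats::runif(1, 0.25, 0.45) * size
      theta <- stats::runif(1, 0, pi)
      xr <- (coords$x - cx) * cos(theta) + (coords$y - cx) * sin(theta)
      yr <- -(coords$x - cx) * sin(theta) + (coords$y - cx) * cos(theta)
      inside <- (xr / ax)^2 + (yr / ay)^2 <= 1
      gradient <- 0.4 + 0.6 * (coords$y - 1) / (size - 1)
      speckle <- stats::runif(size * size, 0.7, 1)
      img <- ifelse(inside, gradient * speckle, 0)
      imgs[[i]] <- matrix(round(img * 256) / 256, size, size)
    }
    stack_slices(imgs)
  })
}
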