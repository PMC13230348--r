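#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG state, restoring the caller's state afterwards.
# All seeded operations in the package funnel through here so that a single
# integer seed fully determines every stochastic result.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Pairwise Euclidean distances between the rows of two matrices (nx x d,
# ny x d) -> nx x ny. Cross-products with clamping against tiny negative
# values from cancellation.
cross_dist <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
  sqrt(pmax(d2, 0))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("synthmetrics_data_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("synthmetrics_numeric_error", "error")))
}

# Half-up rounding to `digits` decimals, matching how human-readable
# confusion-matrix tables are typically printed (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
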