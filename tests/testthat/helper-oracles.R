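# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain double loops and a different linear-algebra
# route than the package internals.

bf_knn_radii <- function(x, k) {
  n <- nrow(x)
  sapply(seq_len(n), function(i) {
    d <- sapply(seq_len(n), function(j) {
      if (i == j) Inf else sqrt(sum((x[i, ] - x[j, ])^2))
    })
    sort(d)[k]
  })
}

bf_manifold <- function(real, synth, k) {
  radii <- bf_knn_radii(real, k)
  n <- nrow(real)
  m <- nrow(synth)
  inside <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      inside[i, j] <- sqrt(sum((real[i, ] - synth[j, ])^2)) <= radii[i]
    }
  }
  list(precision = mean(colSums(inside) > 0),
       density = sum(inside) / (k * m),
       coverage = mean(rowSums(inside) > 0))
}

bf_recall <- function(real, synth, k) {
  bf_manifold(synth, real, k)$precision
}

# Unbiased MMD^2 by exhaustive term enumeration.
bf_mmd2 <- function(x, y, degree = 3, scale = NULL, offset = 1) {
  if (is.null(scale)) scale <- 1 / ncol(x)
  kf <- function(u, v) (sum(u * v) * scale + offset)^degree
  m <- nrow(x)
  n <- nrow(y)
  sxx <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) sxx <- sxx + kf(x[i, ], x[j, ])
  syy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) syy <- syy + kf(y[i, ], y[j, ])
  sxy <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) sxy <- sxy + kf(x[i, ], y[j, ])
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

# Frechet distance via eigenvalues of the (non-symmetric) product Sa Sb —
# a different route to tr((Sa Sb)^{1/2}) than the package's symmetric one.
bf_frechet <- function(mu1, s1, mu2, s2) {
  ev <- eigen(s1 %*% s2, only.values = TRUE)$values
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) -
    2 * sum(sqrt(pmax(Re(ev), 0)))
}

bf_cosine_topk <- function(real, synth, k) {
  idx <- matrix(0L, nrow(real), k)
  sims <- matrix(0, nrow(real), k)
  for (i in seq_len(nrow(real))) {
    s <- sapply(seq_len(nrow(synth)), function(j) {
      sum(real[i, ] * synth[j, ]) /
        (sqrt(sum(real[i, ]^2)) * sqrt(sum(synth[j, ]^2)))
    })
    o <- order(-s, seq_along(s))[seq_len(k)]
    idx[i, ] <- o
    sims[i, ] <- s[o]
  }
  list(indices = idx, similarities = sims)
}

rand_psd <- function(d, seed) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.1
}

rand_rotation <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d)))
}

gm <- function(mu, sigma) {
  structure(list(mean = mu, covariance = as.matrix(sigma), n = NA_integer_),
            class = "gaussian_moments")
}

make_fm <- function(x, source = "real") feature_matrix(as.matrix(x), source, "test")

# Table 1 of the visual Turing test: counts and the printed metrics.
# consistent_* mark printed cells that agree with their own counts.
table1 <- data.frame(
  observer = c(1, 1, 1, 2, 2, 2),
  train_size = c(1000, 2000, 3227, 1000, 2000, 3227),
  TP = c(36, 36, 32, 18, 26, 29),
  FP = c(33, 31, 31, 24, 33, 31),
  TN = c(17, 19, 19, 26, 17, 19),
  FN = c(14, 14, 18, 32, 24, 21),
  accuracy = c(0.53, 0.55, 0.51, 0.44, 0.43, 0.48),
  sensitivity = c(0.72, 0.53, 0.64, 0.32, 0.52, 0.58),
  specificity = c(0.34, 0.38, 0.38, 0.52, 0.34, 0.38),
  consistent_sensitivity = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
)
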