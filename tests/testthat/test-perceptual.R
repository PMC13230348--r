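test_that("turing sessions are balanced, seeded and blinded", {
  reals <- sprintf("r%03d.png", 1:200)
  synths <- sprintf("s%03d.png", 1:500)
  s1 <- build_session(reals, synths, n_each = 50, seed = 7)
  expect_equal(nrow(s1$items), 100)
  expect_equal(sum(s1$key$label == "real"), 50)
  expect_equal(sum(s1$key$label == "synthetic"), 50)
  expect_false("label" %in% names(s1$items))  # presentation list carries no labels

  s2 <- build_session(reals, synths, n_each = 50, seed = 7)
  expect_identical(s1$items, s2$items)
  s3 <- build_session(reals, synths, n_each = 50, seed = 8)
  expect_false(identical(s1$items$ref, s3$items$ref))

  expect_error(build_session(reals[1:10], synths, n_each = 50), "10 real")
})

test_that("responses are scored into the four confusion counts", {
  s <- build_session(sprintf("r%d", 1:60), sprintf("s%d", 1:60), n_each = 50, seed = 1)
  correct <- data.frame(item_id = s$key$item_id, label = s$key$label)
  c1 <- score_responses(s, correct)
  expect_equal(unlist(c1[c("TP", "FP", "TN", "FN")]),
               c(TP = 50, FP = 0, TN = 50, FN = 0))

  all_real <- data.frame(item_id = s$key$item_id, label = "real")
  c2 <- score_responses(s, all_real)
  expect_equal(unlist(c2[c("TP", "FP", "TN", "FN")]),
               c(TP = 50, FP = 50, TN = 0, FN = 0))

  expect_error(score_responses(s, correct[-1, ]), "missing")
  expect_error(score_responses(s, rbind(correct, correct[1, ])), "mismatch")
  bad <- correct; bad$label[1] <- "fake"
  expect_error(score_responses(s, bad), "'real' or 'synthetic'")
})

test_that("a constructed response vector reproduces given confusion counts", {
  s <- build_session(sprintf("r%d", 1:60), sprintf("s%d", 1:60), n_each = 50, seed = 2)
  truth <- s$key$label
  resp <- truth
  # flip 14 reals to "synthetic" (FN) and 33 synthetics to "real" (FP)
  resp[which(truth == "real")[1:14]] <- "synthetic"
  resp[which(truth == "synthetic")[1:33]] <- "real"
  counts <- score_responses(s, data.frame(item_id = s$key$item_id, label = resp))
  expect_equal(unlist(counts[c("TP", "FP", "TN", "FN")]),
               c(TP = 36, FP = 33, TN = 17, FN = 14))
  m <- confusion_metrics(counts)
  expect_equal(m$rounded$accuracy, 0.53)
  expect_equal(m$rounded$sensitivity, 0.72)
  expect_equal(m$rounded$specificity, 0.34)
})

test_that("confusion metrics reproduce every consistent published table cell", {
  for (i in seq_len(nrow(table1))) {
    row <- table1[i, ]
    m <- confusion_metrics(confusion_counts(row$TP, row$FP, row$TN, row$FN))
    expect_equal(m$rounded$accuracy, row$accuracy, info = paste("row", i))
    expect_equal(m$rounded$specificity, row$specificity, info = paste("row", i))
    if (row$consistent_sensitivity) {
      expect_equal(m$rounded$sensitivity, row$sensitivity, info = paste("row", i))
    }
    # exact integer identity: accuracy * total = TP + TN
    expect_equal(m$accuracy * (row$TP + row$TN + row$FP + row$FN), row$TP + row$TN)
  }
  perfect <- confusion_metrics(confusion_counts(50, 0, 50, 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  degenerate <- confusion_metrics(confusion_counts(0, 5, 5, 0))
  expect_true(is.na(degenerate$sensitivity))
})

test_that("cosine neighbours rank exact copies first and handle orthogonality", {
  real <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  synth <- matrix(c(0, 2, 3, 0, 1, 1), 3, 2, byrow = TRUE)
  tab <- cosine_neighbors(real, synth, k = 3)
  expect_equal(tab$indices[1, 1], 2L)            # copy direction of (1,0)
  expect_equal(tab$similarities[1, 1], 1.0)
  expect_equal(tab$similarities[1, 3], 0.0)      # orthogonal vector last
  expect_true(all(diff(tab$similarities[1, ]) <= 0))

  expect_error(cosine_neighbors(rbind(real, c(0, 0)), synth, k = 2), "zero-norm")
  expect_error(cosine_neighbors(real, synth, k = 9), "k must be")
})

test_that("cosine neighbours match the exhaustive oracle and scaling invariance", {
  for (s in 1:10) {
    set.seed(s)
    real <- matrix(rnorm(5 * 6), 5, 6)
    synth <- matrix(rnorm(8 * 6), 8, 6)
    tab <- cosine_neighbors(real, synth, k = 4)
    oracle <- bf_cosine_topk(real, synth, 4)
    expect_equal(tab$indices, oracle$indices)
    expect_equal(tab$similarities, oracle$similarities)

    scaled <- cosine_neighbors(real * 3, sweep(synth, 1, runif(8, 0.1, 5), "*"), k = 4)
    expect_equal(scaled$indices, tab$indices)
    expect_equal(scaled$similarities, tab$similarities, tolerance = 1e-12)
  }
})

test_that("top matches select the highest rank-1 rows with index tie-break", {
  tab <- structure(list(indices = matrix(1:8, 4, 2),
                        similarities = matrix(c(0.9, 0.5, 0.9, 0.7, 0.8, 0.4, 0.8, 0.6), 4, 2),
                        k = 2L), class = "neighbor_table")
  spec <- top_matches(tab, 2)
  expect_equal(spec$real_indices, c(1L, 3L))  # tie at 0.9 -> lower index first
  expect_equal(spec$n_rows, 2)
  expect_equal(spec$n_cols, 3)
  expect_equal(unname(spec$rows[[1]]), c(1L, 1L, 5L))
})

test_that("session files round-trip through CSV", {
  s <- build_session(sprintf("r%d", 1:60), sprintf("s%d", 1:60), n_each = 5, seed = 3)
  items <- withr::local_tempfile(fileext = ".csv")
  key <- withr::local_tempfile(fileext = ".csv")
  write_session(s, items, key)
  k2 <- utils::read.csv(key, stringsAsFactors = FALSE)
  s2 <- session_from_key(k2)
  resp <- data.frame(item_id = k2$item_id, label = k2$label)
  m <- confusion_metrics(score_responses(s2, resp))
  expect_equal(m$accuracy, 1)
})
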