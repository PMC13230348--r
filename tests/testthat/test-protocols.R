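quick_cfg <- function(seed = 1, ...) {
  eval_config(seed = seed, kid_cfg = kernel_config(n_subsets = 10), ...)
}

test_that("identical real and synthetic features give the ideal report", {
  set.seed(1)
  x <- matrix(rnorm(120 * 3), 120, 3)
  r <- run_protocol(make_fm(x), make_fm(x, "synthetic"), quick_cfg())
  expect_equal(r$scores$composite$fid, 0, tolerance = 1e-8)
  expect_equal(r$scores$fidelity$precision, 1)
  expect_equal(r$scores$diversity$recall, 1)
  expect_equal(r$scores$diversity$coverage, 1)
  expect_equal(r$scores$fidelity$alpha_precision, 1)
  expect_equal(r$scores$diversity$beta_recall, 1)
  expect_equal(r$scores$generalization$authenticity, 0)  # exact copies
})

test_that("the ideal scenario scores near-ideal across the metric suite", {
  res <- sapply(1:10, function(s) {
    cl <- gen_feature_clouds(scenario_spec(seed = s))
    r <- run_protocol(cl$real, cl$synth, quick_cfg(seed = s))
    unlist(r$scores)
  })
  m <- rowMeans(res)
  expect_gte(m[["fidelity.precision"]], 0.9)
  expect_gte(m[["diversity.recall"]], 0.9)
  expect_gte(m[["fidelity.density"]], 0.9)
  expect_gte(m[["diversity.coverage"]], 0.9)
  expect_gte(m[["fidelity.alpha_precision"]], 0.9)
  expect_gte(m[["diversity.beta_recall"]], 0.9)
  # nearest-neighbour memorization audit sits near its no-memorization level
  # (~0.58 for an iid generator), far above the copying regime
  expect_gte(m[["generalization.authenticity"]], 0.5)
  # kid is centered at zero for a perfect generator; at this fixture's kernel
  # scale the natural yardstick is its own across-seed dispersion
  kid_vals <- res["composite.kid", ]
  expect_lt(abs(mean(kid_vals)) / (stats::sd(kid_vals) / sqrt(length(kid_vals))), 4)
})

test_that("matched mode subsamples the synthetic set to the real count", {
  cl <- gen_feature_clouds(scenario_spec(n_real = 100, n_synth = 600, seed = 2))
  r <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 2))
  expect_equal(r$n_synth, 100)
  r_fixed <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 2, n_synth = 300))
  expect_equal(r_fixed$n_synth, 300)
  r_all <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 2, n_synth = 600))
  expect_equal(r_all$n_synth, 600)
})

test_that("larger synthetic sets do not reduce expected coverage", {
  covs <- sapply(1:10, function(s) {
    cl <- gen_feature_clouds(scenario_spec(n_real = 150, n_synth = 1500, seed = s))
    md <- knn_radii(cl$real, 5)
    matched <- with_seed(s, sample.int(1500, 150))
    c(matched = manifold_coverage(md, unclass(cl$synth)[matched, ]),
      large = manifold_coverage(md, cl$synth))
  })
  expect_lte(mean(covs["matched", ]), mean(covs["large", ]))
})

test_that("reports serialize to JSON, CSV and Markdown deterministically", {
  cl <- gen_feature_clouds(scenario_spec(n_real = 80, n_synth = 80, seed = 3))
  r <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 3))

  fj <- withr::local_tempfile(fileext = ".json")
  write_report(r, fj, "json")
  back <- read_report_json(fj)
  expect_equal(back$scores$fidelity$precision, r$scores$fidelity$precision)
  expect_equal(back$scores$composite$fid, r$scores$composite$fid)
  expect_equal(sort(names(back$scores)),
               sort(c("composite", "fidelity", "diversity", "generalization")))

  fc <- withr::local_tempfile(fileext = ".csv")
  write_report(r, fc, "csv")
  tab <- utils::read.csv(fc)
  expect_equal(nrow(tab), 10)  # one row per metric, fixed order
  expect_equal(tab$metric, c("fid", "kid", "kid_sd", "precision", "density",
                             "alpha_precision", "recall", "coverage",
                             "beta_recall", "authenticity"))

  fm_ <- withr::local_tempfile(fileext = ".md")
  write_report(r, fm_, "md")
  md <- readLines(fm_)
  expect_true(any(grepl("^## fidelity$", md)))
  expect_true(any(grepl("^## diversity$", md)))
  expect_true(any(grepl("^## generalization$", md)))
})

test_that("identical config and seed reproduce the report bit-for-bit", {
  cl <- gen_feature_clouds(scenario_spec(n_real = 90, n_synth = 120, seed = 4))
  r1 <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 4))
  r2 <- run_protocol(cl$real, cl$synth, quick_cfg(seed = 4))
  expect_identical(r1$scores, r2$scores)
  expect_identical(summary(r1), summary(r2))
})

test_that("feature matrices persist with their JSON sidecar", {
  fmx <- feature_matrix(matrix(rnorm(20), 5, 4), "synthetic", "randproj-x", letters[1:5])
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(fmx, f)
  back <- read_features(f)
  expect_equal(unclass(back), unclass(fmx), ignore_attr = TRUE)
  expect_equal(attr(back, "source"), "synthetic")
  expect_equal(attr(back, "extractor_id"), "randproj-x")
  expect_equal(attr(back, "sample_ids"), letters[1:5])
})

test_that("the command-line front end scores counts and flags bad usage", {
  cli <- system.file("cli", "synthmetrics.R", package = "synthmetrics")
  expect_true(nzchar(cli))
  out <- suppressWarnings(system2("Rscript", c(cli, "turing-score", "--counts", "36,33,17,14"),
                                  stdout = TRUE, stderr = FALSE))
  expect_equal(attr(out, "status"), NULL)  # exit 0
  expect_match(paste(out, collapse = " "),
               "accuracy 0.53 sensitivity 0.72 specificity 0.34", fixed = TRUE)

  bad <- suppressWarnings(system2("Rscript", c(cli, "frobnicate"),
                                  stdout = FALSE, stderr = FALSE))
  expect_equal(bad, 2L)
})
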