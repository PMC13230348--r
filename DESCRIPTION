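Package: synthmetrics
Title: Fidelity, Diversity and Generalization Metrics for Synthetic Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-dimensional evaluation of synthetic medical images against
    real data. Implements composite distribution distances (Frechet distance,
    polynomial-kernel MMD), k-nearest-neighbour manifold metrics (precision,
    recall, density, coverage), hypersphere one-class metrics (alpha-precision,
    beta-recall, authenticity with batched memorization auditing), visual
    Turing-test session construction and confusion-matrix scoring, cosine
    k-NN memorization analysis, a NIfTI 2D-slice preprocessing chain
    (intensity normalization, central-slice extraction, zero-padding,
    stacking), seeded synthetic fixture generators emulating generator
    pathologies (mean shift, mode dropping, jittered copying), and evaluation
    protocols producing grouped, reproducible metric reports.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
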