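---
title: "Evaluating synthetic medical images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic medical images: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthmetrics)
```

## The evaluation problem

A generative model of medical images can fail in three distinct ways: its
outputs can look unrealistic (a fidelity failure), they can cover only part
of the real data distribution (a diversity failure, classically mode
collapse in GANs), or they can be too faithful — near-copies of training
subjects, which defeats the privacy rationale for synthetic data (a
generalization failure). A single composite score cannot separate these.
`synthmetrics` computes a battery of metrics along all three axes on
embeddings of the images, together with the perceptual-evaluation machinery
(visual Turing tests, cosine nearest-neighbour displays) that complements
them.

Everything downstream of the extractor operates on an `n × d` feature
matrix. The package deliberately treats the extractor as a contract — any
deterministic map from an image to a fixed-length vector — and ships two
weight-free implementations (pixel flattening and a seeded Gaussian random
projection). Pretrained-CNN embeddings can be plugged in behind the same
contract; none are bundled, because distributing weights is out of scope and
nothing in the metric layer depends on which extractor produced the rows.

## Preprocessing chain

Volumes are prepared for 2D evaluation by: per-volume min–max normalization
to [0, 1] (per volume, not per slice, so relative intensities across a
subject's slices survive); extraction of the central axial slice; centered
zero-padding onto a square canvas (256 px by default); and stacking into a
single `H × W × N` NIfTI volume, one slice per subject.

Two conventions here are genuinely underdetermined and are fixed as
follows. The "central" slice of a `Z`-deep volume is taken at 0-based index
`floor(Z/2)` — deterministic, the true middle for odd `Z`, the upper-middle
for even `Z`, and overridable via an explicit index argument. Padding splits
any odd margin as `floor(pad/2)` on the top/left; a 182 × 218 slice on a 256
canvas therefore gets margins of 37 and 19. Padding preserves the intensity
sum exactly, and stacks are written as 32-bit floats with an identity-scaled
affine; data quantized to a 1/256 grid (as the phantom generator produces)
round-trips bit-exactly.

## Composite metrics

**Fréchet distance.** Real and synthetic embeddings are summarized by their
sample mean and covariance (divisor `n − 1`) and compared with
`‖μ_r − μ_s‖² + Tr(Σ_r + Σ_s − 2(Σ_r Σ_s)^{1/2})`. The cross term is
computed from the symmetric eigendecomposition of `Σ_r^{1/2} Σ_s Σ_r^{1/2}`,
which is numerically stable and keeps every intermediate symmetric.
Eigenvalues below `−10⁻⁶` (relative) abort with an error; smaller negatives
are rounding artifacts and are clipped to zero, as is a slightly negative
final value. The unit tests cross-check this route against an independent
one (eigenvalues of the non-symmetric product `Σ_r Σ_s`) to `10⁻⁸`.

**Kernel distance.** The unbiased MMD² estimator under the cubic polynomial
kernel `k(u, v) = (uᵀv/d + 1)³` — degree 3, scale `1/d`, offset 1, the
standard choice for this metric — averaged over `n_subsets = 100` seeded
random subsets of `m = min(n, 1000)` samples per side, reporting the mean
and the across-subset standard deviation. Because the estimator is unbiased,
its expectation is 0 for a perfect generator; its *magnitude* scales with
the kernel values, so scores are only comparable across models evaluated on
the same embedding. On fixtures with large mean vectors the raw values are
large; this is a property of the kernel, not a defect.

## k-NN manifold metrics

The support of each distribution is estimated as a union of Euclidean
spheres: each sample's sphere has radius equal to the distance to its k-th
nearest other sample (self excluded, neighbour ties broken by smaller
index). Precision/recall use `k = 3` and density/coverage use `k = 5` —
the choices of the papers that introduced each metric pair; both are
exposed in `eval_config()`. Search is exact (`O(n²)` distance matrices);
at the tens-of-thousands scale this toolkit targets, approximate indices
are unnecessary complexity.

Two estimator properties matter for interpretation and are verified as
tests. First, a single extreme real outlier inflates precision (its huge
sphere swallows distant synthetic points) but not density, which is the
design motivation for density/coverage. Second, all four scores are
finite-sample quantities: for a *perfect* generator with `n = m = 400` and
`d = 4`, precision and recall sit near 0.93, not 1.0 — the k-NN spheres of
one iid sample do not cover every point of another. Expected near-ideal
levels, not 1.0, are the right reference when reading real reports.

## Hypersphere (one-class) metrics

α-precision, β-recall and authenticity are defined on a one-class embedding
in which typical real samples sit near a center and outliers near the
boundary. The original construction trains a one-class network; its
architecture and loss are not part of the metric's definition. This package
instead uses a deterministic whitening transform: the center is the real
mean, and each sample's radius is its Mahalanobis-style distance under the
real covariance with a ridge `ε = 10⁻⁶ · tr(Σ)/d`. This satisfies the
contract (typical points near the center, outliers far, rotation-invariant
radii), is exactly reproducible, and needs no training; a learned one-class
objective can be substituted behind the same interface. A rank-deficient
covariance triggers a warning and relies on the ridge; a zero-variance
fitting set degenerates gracefully to the identity map (all radii 0).

**α-precision.** For each level α of a 20-point grid (0.05…1.00),
`P(α)` is the fraction of synthetic radii at or below the α-quantile
(nearest-rank) of real radii. A calibrated generator has `P(α) = α`; both
over-dispersion (`P < α`) and over-concentration (`P > α`) are penalized by
the summary `1 − 2 ∫|P(α) − α| dα`, integrated by trapezoid over the grid
anchored at (0, 0) and clipped to [0, 1]. With aligned grids and no radius
ties, identical real and synthetic embeddings score exactly 1.

**β-recall.** The diversity mirror: thresholds come from the synthetic side
and membership is counted over real samples. A naive mirror that only swaps
the radius distributions is provably uninformative — with a shared center,
the fraction of real radii below synthetic quantiles is the reflection of
the α-curve about the diagonal, so the two summaries would always coincide
and mode collapse would be invisible. The implemented construction instead
anchors the β-support at the synthetic center (the mean of the mapped
synthetic cloud): a real sample is β-covered when its nearest synthetic
neighbour is β-typical (center distance within the β-quantile, nearest-rank,
of the nearest-neighbour center distances) and the real sample lies within
that neighbour's center-distance ball. Identical embeddings still score
exactly 1, a synthetic cloud collapsed onto the center scores 0, and mode
collapse now shows up as α high / β depressed, which is the pattern the
metric pair exists to expose.

**Authenticity.** For each real sample the audit asks whether its nearest
neighbour across the pooled mapped space is a synthetic sample (strictly
closer than the nearest other real). Each flagged real's arg-min synthetic
is its memorizer; memorizers are deduplicated within a batch and the batch
score is `1 − (#memorizers)/(batch size)`. Synthetic samples are partitioned
into seeded disjoint batches of the real-set size until the target count
(default 50,000, capped at what exists) is covered; the final partial batch
is kept and weighted by its own size, so the overall value equals
`1 − (total memorizers)/(total synthetic audited)`. Disjoint batches were
chosen over resampling: they cover the target count without double-counting
and keep the partition a pure function of the seed.

One property of this estimator deserves emphasis because it is easy to
misread: a *perfect, non-memorizing* generator does not score 1. For iid
synthetic data of the real distribution with matched counts, each real's
nearest neighbour is synthetic with probability ≈ 1/2, so the no-memorization
reference level is ≈ 0.55–0.65 (the package's ideal-scenario tests observe
≈ 0.58 and assert ≥ 0.5). The score approaches 1 only when synthetic samples
keep more distance from the reals than the reals keep from each other, and
it falls monotonically toward 0 as synthetic samples become jittered and
then exact copies — the regime the audit exists to detect, and the regime
in which its value is interpretable.

## Perceptual evaluation

Turing sessions draw `n_each` real and synthetic references without
replacement and shuffle them with the seed; the presentation list carries no
labels and the answer key is a separate table, so sessions are blinded by
construction. Scoring maps responses to `TP` (real called real), `FN`, `TN`
(synthetic called synthetic), `FP`, and reports accuracy, sensitivity and
specificity at full precision plus 2-decimal half-up rounding, matching how
such tables are conventionally printed. Published confusion tables can
contain internal inconsistencies; this package always computes the metrics
from the counts. The cosine k-NN table ranks, for each real embedding, the
`k = 4` most similar synthetic embeddings (ties by smaller index), and the
montage selector displays the two reals with the highest rank-1 similarity
beside their neighbours.

## Fixture generators

`gen_feature_clouds()` emulates, in embedding space, the three generator
pathologies the metrics must detect: a global synthetic mean shift
(fidelity), dropped mixture modes (diversity), and jittered copies of real
rows (memorization). The default scenario is two spherical Gaussian modes
of unit sd with centers 8 sd apart in `d = 4` dimensions and
`n = 400` samples per side — separation ≥ 6 sd makes cross-mode sphere
membership vanishingly improbable, so geometric expectations (e.g. "recall
falls to the retained-mode mass") hold almost surely and brute-force oracles
are exact. These sizes also keep the full suite and the acceptance script in
the seconds-to-minutes range. `gen_phantom_stack()` produces elliptical
"phantom" slices (randomized axes and orientation, vertical intensity
gradient, speckle) to exercise the image → embedding → metric path end to
end.

What the fixtures do *not* emulate: real MRI embeddings are not Gaussian
mixtures, real extractors are not random projections, and real sample sizes
(thousands of reals, tens of thousands of synthetics) amplify the
sample-size sensitivities only directionally visible at desk scale. Passing
fixture tests therefore certifies the *estimators* — their definitions,
determinism and sensitivity directions — not any particular generative
model's quality.

## Determinism

Every stochastic step (mixture sampling, subset draws, batch partitions,
session shuffles) runs under a locally scoped seed that is restored
afterwards, so identical configuration + seed reproduces every score
bit-for-bit and library code never perturbs the caller's RNG state. The
evaluation protocol's matched mode subsamples the synthetic set to the real
count without replacement using the config seed, mirroring the practice of
reporting metrics both at a fixed large synthetic count and at a count
matched to the real set — coverage in particular is systematically higher
when synthetic samples vastly outnumber real ones, which the test suite
checks as a directional property.

## Known limitations

- No pretrained embedders are shipped; published FID/KID/precision values
  for specific models are reproducible only with the original images and
  extractor weights.
- Exact `O(n²)` neighbour search bounds practical sample counts to roughly
  10⁴–10⁵ per side.
- The whitening one-class transform captures second-order typicality only;
  a trained one-class network can reorder which samples count as outliers,
  changing α/β/authenticity at the margins.
- The Turing-test tooling scores sessions; the interactive viewing
  application (window/level adjustment) is outside the package.
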