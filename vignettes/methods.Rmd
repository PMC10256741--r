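---
title: "Models and methods behind langlat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind langlat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`langlat` implements a three-part analysis: classification of subjects
into language lateralization phenotypes from five functional metrics,
estimation of hemispheric asymmetries in macroscale connectivity
gradients, and variance-components heritability of both. This vignette
documents the models, their assumptions, the tunable parameters, and the
numerical and design choices, in the package's own terms.

## The five lateralization metrics

Each subject is described by a `LanguageFeatureVector` of five numbers.
Two come from task-contrast betas on the language atlas: the network
asymmetry (mean beta over left language ROIs minus right) and the hub
asymmetry (same, over the hub ROIs — inferior-frontal and posterior
superior-temporal regions). Three come from resting connectivity: the
mean Fisher-z correlation over homotopic language pairs, and the sum and
L−R difference of the hemisphere-average language "strength" (each
region's summed correlation to the other same-hemisphere language ROIs).

Assumptions and conventions:

- Per-scan Pearson correlations are averaged in Fisher-z space and
  back-transformed by `tanh`; the z average is the subject's connectivity
  matrix. Averaging in z is variance-stabilizing and is the order used
  throughout.
- `|r|` is clipped at `1 - 1e-7` before `atanh` so degenerate inputs
  (perfectly collinear synthetic series) keep finite z. The clip is a
  `build_connectivity()` argument.
- Strength is computed on r-scale values (after the back-transform), the
  self-correlation is excluded, and negative correlations enter the sum
  as-is — no rectification or thresholding. Summing over the *other*
  same-hemisphere ROIs (n−1 terms) rather than including a self term only
  shifts the metric by a constant and leaves every asymmetry unchanged;
  the package fixes the self-excluded reading.
- The connectivity diagonal is stored as 0 and excluded from all sums.

Mirror antisymmetry is the structural test of these definitions: swapping
the hemispheres of a subject negates the three asymmetry metrics exactly
and leaves the two symmetric metrics unchanged (enforced to 1e-12 in the
test suite).

## Phenotype classification

Features are z-standardized column-wise (SD scaling; the scale estimator
is a deliberate, recorded choice) and clustered with Ward's
minimum-variance criterion on Euclidean distance. The package uses the
Ward.D2 variant — squared distances inside the Lance–Williams update, so
merge heights are in distance units — which is the common modern default
for "Euclidean + Ward"; the full dendrogram is checked against an
independently coded O(n³) Lance–Williams reference in the tests.

The cluster count is fixed at k = 3 by design: the three-group solution
(strong typical, mild typical, atypical) is the committed choice of the
analysis this package operationalizes. As a supporting diagnostic,
`cluster_stability()` reports, per k, the mean bootstrap Jaccard
similarity between full-data clusters and their best-matching clusters on
resampled data. This deliberately replaces a multiscale-bootstrap
"approximately unbiased" p-value and multi-index cluster-count suites
with a single transparent statistic: it preserves the intent (is k = 3
stable under resampling?) at a fraction of the machinery.

Clusters are *named* by ranking their mean network task asymmetry;
ties are broken by hub asymmetry. If the lowest-ranked cluster's mean is
not negative it is still named atypical, with a warning — the naming is
ordinal, not a sign test.

## Connectivity gradients

Per subject, the whole-cortex matrix is processed as:

1. **Row sparsification** — the top `ceiling(0.1 · (n−1))` off-diagonal
   entries per row are kept *by signed value* (strongest positive
   coupling, not absolute magnitude; a config switch). Ties at the cutoff
   keep the lowest column index, for determinism. The result is
   asymmetric by construction.
2. **Normalized-angle affinity** — `s_ij = 1 − arccos(cosine(row_i,
   row_j))/π`, symmetric with unit diagonal, in (0, 1] for non-opposed
   rows.
3. **Diffusion map embedding** — anisotropic normalization
   `W = D^{-α} S D^{-α}` with α = 0.5, transition operator
   `P = D_w^{-1} W`, eigendecomposition through the symmetric conjugate
   of P. The trivial constant eigenvector (λ = 1) is dropped; components
   are scaled by `λ/(1−λ)` (diffusion time 0, "multiscale") or `λ^t`.
   α and t are exposed in `gradient_config()` and set to the
   conventional defaults of this embedding family; variance explained is
   reported as `λ_i²/Σλ_j²` over the nontrivial spectrum — one of several
   normalizations in use, recorded here because no downstream result
   depends on it.
4. **Procrustes alignment** — each subject's embedding is aligned to a
   group template by the orthogonal (rotation/reflection, no scaling, no
   translation) transform minimizing Frobenius distance; the template is
   the embedding of the cohort-mean connectivity matrix (z-averaged, then
   back-transformed) and is refreshed as the mean of aligned individuals
   over 10 iterations. The group-matrix definition is a recorded design
   choice; it is standard practice where the source methodology leaves
   the template unspecified.
5. **Sign convention** — eigenvector signs are arbitrary, so template
   components are flipped to correlate positively with the
   within-hemisphere region order (the association end of the synthetic
   latent axis); individuals inherit the orientation through alignment.
6. **Min–max scaling** to 0–100 per subject over the whole brain (both
   hemispheres jointly), then per-network L−R asymmetries.

Degenerate inputs fail loudly: all-zero rows (after sparsification), a
disconnected positive-affinity graph, non-symmetric affinities, and
constant components under min–max scaling are errors, not silent
repairs.

## Group statistics

Each outcome (a feature, or one network × gradient asymmetry) is modeled
by OLS with the phenotype, the covariates age, sex, handedness class and
intracranial volume, and the handedness × phenotype interaction. The
phenotype main effect uses a Type-II F test (respecting marginality in
the presence of the interaction); Type II is a recorded choice where the
source analysis does not state the sum-of-squares type. Post-hocs are
Tukey's range test across the three phenotypes for the feature analyses
and plain two-sided pooled-variance Student t for the binary
typical-vs-atypical gradient contrasts. Network-level families are
Bonferroni-corrected for 7 tests (raw p ≤ 0.007 at the 5% family level).
Handedness class uses the score-below-30 left-hander cut. If a small
cohort leaves a handedness × phenotype cell empty, the interaction is
inestimable; the model is refit without it, with a warning — preferable
to failing on legitimate small samples.

## Heritability

The polygenic model is `y ~ N(Xβ, σ²_g·K + σ²_e·I)` with K the kinship
relatedness 2Φ (1 within MZ pairs, 0.5 within DZ/full-sibling pairs, 0
across families, unit diagonal — no inbreeding). The fit maximizes the
Gaussian likelihood over `h² = σ²_g/(σ²_g+σ²_e) ∈ [0, 1)` after a single
eigendecomposition of K, which diagonalizes the covariance and makes each
profile-likelihood evaluation O(n). ML (not REML) is used so that
likelihood-ratio tests against the nested `σ²_g = 0` null are coherent;
since the null sits on the boundary, the LRT p-value uses the 50:50
mixture `p = 0.5·P(χ²₁ ≥ T)` with p = 1 at T = 0. Standard errors come
from the numeric observed information of the profile log-likelihood; at
the h² = 0 boundary the curvature is evaluated just inside the domain and
the SE should be read as approximate (a fit with no interpretable
curvature reports `NA`).

Recorded choices: the binary phenotype (typical/atypical) is analyzed as
a 0/1 quantitative trait — a liability-threshold model is out of scope
and the 0/1 treatment is a known simplification; no shared-environment
component is modeled; unrelated singletons are included (they inform
σ²_e and the covariate effects); the heritability covariates are age,
sex, age², age×sex, age²×sex, handedness and intracranial volume.

## The synthetic cohort generator

`simulate_cohort()` produces data *with the statistical structure the
analysis assumes*, not biophysically realistic fMRI:

- **Latent gradient coordinate.** Regions are equally spaced on [0, 1]
  within each hemisphere (identical ordering across hemispheres), and
  region covariance decays as `exp(−|g_i−g_j|/bandwidth)` (bandwidth
  0.3), damped by 0.35 across hemispheres, plus within-network (+0.15)
  and homotopic (+0.25) coupling. The homotopic default puts homotopic
  language correlations near 0.6 on the r scale, the range reported for
  such cohorts. Because the true first axis is known, gradient-recovery
  tests are possible; the tests require the median |correlation| between
  subject G1 and the latent coordinate to reach 0.8, and observe ≈0.97
  at 21 regions per hemisphere.
- **Groups and effects.** Group proportions default to 48/44/8%
  (strong/mild/atypical). Task-beta asymmetries use the published group
  means as effect sizes: network 1.74/0.70/−0.96, hubs 2.64/1.17/−1.16
  (contrast units); non-hub language effects are solved so the
  network-level mean is exact even though hubs carry a larger effect.
  Language-block connectivity boosts (left and right separately, per
  group) make the strength metrics group-informative with an
  approximately bilateral atypical profile.
- **Within-group spread.** The source material reports group means with
  standard errors but not the within-group SD of the latent asymmetry,
  so the generator exposes it as free parameters chosen once: beta noise
  SD 0.45 per region and hemisphere (≈0.21 SD on the network asymmetry),
  which makes the three groups separable in the five-feature space — the
  regime in which a clustering-based phenotype is meaningful.
- **Heritability.** A liability with additive-genetic structure
  (covariance h²·2Φ within families, default h² = 0.3) drives both group
  assignment (by its N(0,1) quantiles at the configured proportions — so
  MZ co-twins agree more often than strangers, increasingly with h²) and
  a group-centered modulation of the effect sizes (`1 + 0.15·u`, with u
  the liability minus its truncated-normal group mean, keeping group
  means exact).
- **Determinism.** Every subject has an RNG stream derived from (master
  seed, subject index); identical configs give byte-identical cohorts,
  and cohorts are stable under subject-count changes.
- **Positive definiteness** of the assembled covariance is enforced by
  eigenvalue clipping at 1e-6 — simple and deterministic.

What the generator does *not* emulate: hemodynamics, motion, scanner
drift, spatial geometry, parcellation error, non-Gaussian tails. Passing
tests therefore demonstrate the correctness and calibration of the
*pipeline* under the assumed generating model, not robustness to real
acquisition artifacts.

## Problem sizes and numerical tolerances

The test and acceptance runs use desk-scale sizes chosen as the package's
own defaults: phenotype recovery on 1000 subjects at 18 regions per
hemisphere; gradient analyses at 21–40 regions per hemisphere with 4
scans × 200 time points; heritability recovery over 50 replicates at
300 MZ + 300 DZ pairs and LRT calibration over 1000 null replicates at
100 + 100 pairs. Exact-arithmetic identities are asserted at 1e-10–1e-12;
eigendecomposition-based comparisons at 1e-8 (up to component sign);
Monte-Carlo quantities at tolerances derived from their sampling SDs.

## Known limitations

- The 0/1 treatment of the binary phenotype underestimates
  liability-scale h²; treat that estimate as ordinal evidence, not a
  point value.
- The bootstrap-Jaccard stability score is not an AU p-value; its
  absolute level is not comparable across methods, only across k within
  a dataset.
- Procrustes alignment assumes the individual and template spectra are
  comparable; with very few regions the higher components can rotate
  freely and per-network G2/G3 asymmetries become noisy.
- REML is not implemented; ML variance components carry the usual small
  downward bias in small samples.
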