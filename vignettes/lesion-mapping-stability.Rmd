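---
title: "Ground-truth simulation of lesion-deficit mapping stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-truth simulation of lesion-deficit mapping stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lesion-deficit (lesion-symptom) mapping asks which brain regions, when
damaged, cause a behavioural deficit. The classical approach is
mass-univariate: test each region's lesion load against the deficit score
independently and control the family-wise error rate. Multivariate
alternatives — here, L1-penalized ("lasso") regression — model all regions
jointly and implicate the regions that retain non-zero coefficients.

Stroke lesion data are observational and extremely multicollinear: lesions
respect vascular territories, so the lesion loads of neighbouring regions
co-vary strongly. Under such collinearity, many different sparse models
explain the data almost equally well, and non-zero coefficients can be
exchanged between correlated regions without changing the fit. A mapper may
therefore identify a region that *predicts* the deficit without being its
cause. This package provides a ground-truth simulation framework to measure
that problem: because the deficit is simulated from known regions, the
sensitivity, specificity and — via repeated subsampling — the *stability* of
each mapper's selections can be evaluated objectively.

`lesionstab` implements the full pipeline: a synthetic lesion-cohort
generator with a controllable collinearity knob, atlas-based lesion-load
extraction, deficit simulation with calibrated noise, both mappers, and the
subsample-and-count stability procedure.

## The synthetic cohort generator

No patient lesion masks are distributed with the package; the generator
stands in for a stroke cohort. It emulates the study configuration the
pipeline is designed around: 180 subjects, a 116-region whole-brain
parcellation, lesion loads in [0, 1] with many zero-load regions per
subject, and strong positive inter-region load correlation.

* **Atlas** (`generateAtlas`): an ellipsoidal "brain" foreground inside a
  20 × 24 × 20 voxel grid (≈ 4300 foreground voxels), tiled into 116
  contiguous regions by seeded multi-source region growing. Regions are
  roughly equal-sized blocks; no anatomical semantics are implied.
* **Territories** (`makeTerritories`): regions are grouped into 12 spatial
  clusters by farthest-point seeding on region centroids — a stand-in for
  vascular territories. Twelve clusters of ~10 regions give territory sizes
  at which a median lesion can plausibly span several regions of its
  territory.
* **Lesions** (`generateLesionMasks`): each subject receives one contiguous
  lesion grown from a random foreground voxel on the 6-connected voxel
  graph. A candidate voxel is always accepted inside the seed region,
  accepted with probability `withinTerritorySpread` in another region of the
  same territory, and with probability `0.1 * withinTerritorySpread` outside
  it; rejected voxels leave the frontier permanently, so growth terminates.
  This is the simplest contiguity-preserving mechanism with a single
  collinearity knob: within-territory load correlation increases
  monotonically with the spread parameter (verified empirically in the test
  suite over a spread grid at 500 subjects).
* **Defaults**: lesion extent is log-normal with median 150 voxels
  (sdlog 0.7) on the default grid — large enough that a typical lesion spans
  ~4 regions, the regime in which collinearity matters; spread 0.8, giving
  mean within-territory load correlations well above the between-territory
  baseline. No real cohort's lesion-size distribution or collinearity level
  is being estimated here: these defaults are configuration, not claims
  about any real cohort.

What the generator does **not** emulate: anatomically realistic vascular
territories, heterogeneous region sizes (real atlas regions vary by an
order of magnitude), registration error, multifocal lesions, or lesion-size
covariates of behaviour. Passing tests therefore demonstrate properties of
the mappers under controlled multicollinearity, not performance guarantees
on real cohorts.

## Deficit simulation

`simulateDeficit` builds the ground truth: the deficit equals the lesion
load of one target region (or a non-negative weighted sum of several), plus
i.i.d. normal noise

```
scores = signal + eps,   eps ~ N(0, (k · SD(signal))^2)
```

with `k = 0.2` (low noise) and `k = 1.0` (high noise) as the two study
conditions. Two readings of "SD" were possible; the package uses the sample
SD of the simulated signal itself, computed once on the full cohort before
any subsampling — the only reading under which the noise level is a fixed
property of the simulation rather than of each subsample. Likewise the noise
is drawn once per deficit and shared across all subsampling repetitions
(matching the order *simulate the deficit, then subsample repeatedly*); this
means repetition-to-repetition variability reflects subsampling only.

The multi-region ("complex") scenario uses `complexDeficitWeights`: a
reproducible draw of 8 regions with simplex weights, combined with `k = 1.0`
noise. It is an explicit stand-in for real neuropsychological scores, which
are not distributable — it emulates a deficit with many contributing regions
and heavy measurement noise, not any particular cognitive function.

## The univariate mapper

`univariateMap` computes each region's Pearson correlation with the deficit
and the exact two-sided p-value through the null t-transform
`t = r sqrt((n−2)/(1−r²))` with `n − 2` degrees of freedom. Selection uses
Bonferroni control at family-wise `alpha = 0.05`; the divisor is always the
*full* atlas region count R, even when some regions are untestable
(constant load in the analysed sample) — this matches a correction applied
to the full 116-region family and is never anti-conservative. Untestable
regions are reported with `r = NA`, `p = 1`, never selected, rather than
given a fabricated zero correlation. Tests are two-sided, the conservative
default. The Bonferroni FWER bound is verified in the test suite by
Monte-Carlo simulation under a global null on collinear loads.

## The lasso mapper

`lassoFit` minimizes

```
(1/(2n)) ||y − Xb||² + λ ||b||₁
```

by cyclic coordinate descent with soft-thresholding, implemented in C++
with covariance updates and active-set sweeps, warm starts along a
decreasing λ path, and a convergence tolerance of 1e−7 on the standardized
coefficients. The Karush-Kuhn-Tucker optimality conditions are verified at
every exit. Columns are standardized (mean 0, unit n−1 SD) before
penalization and coefficients reported on the original scale; zero-variance
columns are carried as structural zeros. The solver's correctness is tested
against three independent oracles: the analytic all-zero threshold λ_max,
the closed-form soft-threshold solution on orthonormal designs, and a
generic convex optimizer (box-constrained L-BFGS-B on the positive/negative
coefficient split) on random instances.

`lassoCv` selects the penalty by K-fold cross-validation (K = 5 in the
study design): a seeded random partition into near-equal folds, a 100-point
λ grid log-spaced from λ_max down to λ_max·1e−3, standardization refit
inside each training fold, and held-out MSE aggregated over all subjects.

**Penalty rule.** Two standard rules are implemented: the exact CV-MSE
minimizer (`"min"`, ties towards the larger penalty) and the one-standard-
error rule (`"1se"`: the largest penalty within one SE of the minimum). The
package default is `"1se"`. This was a genuinely open design choice, and it
matters: under the strong collinearity of lesion data the CV-minimum rule
systematically over-selects (on the default cohort it retains ~5–9 regions
per subsample where one region is causal — behaviour confirmed
independently with `glmnet::cv.glmnet`'s `lambda.min` on the same
subsamples), whereas the 1-SE rule retains the causal region plus at most a
couple of correlated neighbours. Only the 1-SE rule reproduces the
near-perfect single-region recovery that this simulation design is known to
produce; it is also the conventional choice when the lasso is used for
*selection* rather than prediction. Implicated regions are exactly those
with a non-zero coefficient — soft-thresholding produces exact zeros, so no
additional magnitude threshold is applied.

## The stability pipeline

`runStability` repeats, `nReps = 100` times: draw `subsampleSize = 120` of
the 180 subjects without replacement (two-thirds), run each mapper on the
subsample, record the selected-region set. Repetition *i* uses the child
seed `masterSeed XOR i`, so any single repetition can be reproduced in
isolation. Both mappers see the same subsample within a repetition. A
mapper failure on a subsample is recorded as an empty selection with a
warning rather than aborting, keeping the denominator fixed at `nReps`.

The outcome measure is the per-region occurrence count across repetitions.
`summarizeStability` adds the report table (regions with count ≥ threshold,
sorted by count, ties by region id) and three metrics that make
"sensitivity", "specificity" and "stability" quantitative:

* `trueRegionFrequency` — occurrence count of each ground-truth region
  divided by `nReps`;
* `meanFalsePositives` — mean number of selected non-truth regions per
  repetition;
* `pairwiseJaccard` — mean Jaccard similarity |A∩B| / |A∪B| of the selected
  sets over all repetition pairs; two empty selections count as identical
  (Jaccard 1).

`runExperiment` orchestrates a scenario grid (by default the four cells:
target regions 2 and 64 × noise 0.2 and 1.0) and writes per-cell occurrence
CSVs, metrics JSON and bar-chart figures; `runExperimentFromConfig` drives
the whole pipeline from a validated YAML configuration and writes a manifest
from which the run can be reproduced byte for byte.

## Numerical and degenerate-input choices

* Coordinate-descent tolerance 1e−7 (standardized scale); λ-grid floor
  λ_max·1e−3; CV ties resolved towards the larger (sparser) penalty.
* Float NIfTI masks binarize at 0.5, tolerating interpolation artefacts;
  the NIfTI affine is used only for grid-compatibility checks (no
  resampling).
* Per-region SDs use the unbiased n−1 denominator.
* Constant deficit vectors, zero-variance signals with positive noise,
  fewer distinct responses than folds, lesion extents exceeding the
  foreground, and impossible atlas tilings all raise explicit errors.
* All randomness is seeded; every seeded function restores the caller's RNG
  state.

## Problem sizes in the test suite

The packaged tests run the full study configuration (180 × 116, 100
repetitions of 120) for the headline pattern checks, 400–2000 Monte-Carlo
datasets for the calibration checks, and 500-subject cohorts for the
collinearity-monotonicity property; solver oracles use 50 random instances
of size 25–30 × 8–10. These sizes were chosen so the whole suite documents
the method at full design scale while remaining comfortably runnable on a
single CPU.

## Known limitations

* The generator's equal-sized blocky regions and single-lesion-per-subject
  design understate the heterogeneity of real cohorts; absolute
  false-positive rates and stability values should not be read as estimates
  for real data.
* The complex-deficit scenario is a synthetic stand-in for real
  neuropsychological outcomes; conclusions about real deficits require real
  scores.
* The lasso is the only multivariate mapper implemented; game-theoretic and
  kernel-based mappers are out of scope.
* Inference remains associational throughout: even a stable, specific
  selection under this pipeline does not establish causality in
  multicollinear observational data — quantifying that gap is precisely
  what the framework is for.
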