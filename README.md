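# lesionstab

Ground-truth simulation of lesion-deficit mapping stability.

## The problem

Lesion-symptom mapping infers which brain regions, when damaged, cause a
behavioural deficit, from per-subject lesion masks and behavioural scores.
Mass-univariate mapping (one Pearson test per region, Bonferroni-corrected)
is easy to interpret but blind to the joint structure of the brain;
multivariate sparse regression (the lasso) models all regions at once. Both
face the same obstacle: stroke lesion data are an epitome of
multicollinearity — lesion loads of regions sharing a vascular territory
co-vary strongly — so many different sparse models explain the data equally
well and a selected region need not be the causal one.

`lesionstab` packages the simulation design that makes this measurable. A
deficit is *simulated* from known regions, so a mapper's sensitivity and
specificity are objective quantities; repeating each mapper on random
subsamples (100 draws of 120 of 180 subjects) and counting how often every
region is implicated measures the *stability* of its selections. The package
is aimed at methodologists who want to benchmark lesion-deficit inference
procedures under controlled multicollinearity.

## What is inside

* **Synthetic cohort generator** — a toy 116-region atlas volume, one
  contiguous lesion per subject grown with a territory-biased region-growing
  process whose single knob tunes inter-region load correlation
  (`generateAtlas`, `generateLesionMasks`, `makeTerritories`).
* **Lesion-load extraction** — `values[s, r] = |mask_s ∩ region_r| /
  |region_r|` from NIfTI masks + atlas (`extractRegionLoads`,
  `loadCohortFromDisk`).
* **Deficit simulation** — `scores = signal + eps`,
  `eps ~ N(0, (k · SD(signal))²)`, with `k = 0.2` / `1.0` as the low/high
  noise conditions (`simulateDeficit`, `complexDeficitWeights`).
* **Mappers** — `univariateMap` (exact t-transform p-values, Bonferroni over
  the full 116-region family) and `lassoCv` (coordinate-descent lasso in
  C++, 5-fold cross-validated penalty, selected regions = non-zero
  coefficients).
* **Stability pipeline** — `runStability`, `summarizeStability`,
  `runExperiment`, `runExperimentFromConfig`: per-region occurrence counts,
  true-region frequency, mean false positives, pairwise Jaccard stability,
  reproducible from a single master seed and a YAML manifest.

A thin command-line wrapper over these functions ships at
`inst/cli/lesionstab.R` (subcommands `simulate-cohort`, `extract-loads`,
`simulate-deficit`, `map-univariate`, `map-lasso`, `stability`,
`run-experiment`).

## Worked example

```r
library(lesionstab)

atlas  <- generateAtlas(c(20, 24, 20), nRegions = 116, seed = 1)
cohort <- generateLesionMasks(atlas, cohortSpec(seed = 1))
loads  <- extractRegionLoads(cohort, atlas)
loads
#> LoadMatrix: 180 subjects x 116 regions, mean load 0.0375, 0 constant region(s)

## ground truth: damage to region 2 causes the deficit; low noise
deficit <- simulateDeficit(loads, region = 2, noiseK = 0.2, seed = 2)

cfg <- stabilityConfig(nReps = 100, subsampleSize = 120, masterSeed = 7)
tab <- runStability(loads, deficit, cfg)
summarizeStability(tab, truth = 2L, threshold = 10L)
#> stabilitySummary (threshold 10, truth: 2)
#>   univariate 11 region(s) reported; 11.00 selections/rep; Jaccard 1.000; truth freq 1.00; 10.00 false positives/rep
#>   lasso      5 region(s) reported; 2.97 selections/rep; Jaccard 0.483; truth freq 1.00; 1.97 false positives/rep
```

Reading the output: across 100 subsamples the univariate mapper implicates
the true region every time — along with ten other regions every time (its
Bonferroni-significant set is dominated by regions merely correlated with
the truth). The lasso also recovers the truth in 100/100 repetitions but
selects under three regions per repetition (under two false positives),
i.e. it is far more specific; its selection sets still fluctuate across
subsamples (mean pairwise Jaccard 0.48) because non-zero coefficients can
migrate between correlated neighbours — the exchangeability that makes
causal attribution under multicollinearity hard.

`plotStabilityCounts(tab, "lasso", truth = 2L)` draws the occurrence-count
bar chart; `runExperimentFromConfig("experiment.yaml")` runs a whole
scenario grid and writes counts, metrics, figures and a reproducibility
manifest.

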