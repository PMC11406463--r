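#' Construct a cohort specification
#'
#' Defaults describe the study cohort the generator emulates: 180 subjects,
#' 116 atlas regions grouped into 12 vascular-territory-like clusters, lesion
#' extents log-normal with a median of 150 voxels on the default 20 x 24 x 20
#' grid, and a within-territory spread of 0.8 producing strong positive
#' inter-region load correlation.
#'
#' @param nSubjects number of subjects.
#' @param nRegions number of atlas regions.
#' @param territoryPartition optional integer vector assigning each region to
#'   a territory; when empty the partition is derived from atlas geometry.
#' @param nTerritories number of derived territory clusters.
#' @param withinTerritorySpread probability in \[0,1\] that lesion growth
#'   crosses into an adjacent region of the same territory.
#' @param lesionSize lesion extent distribution, see [CohortSpec-class].
#' @param seed RNG seed.
#' @return A [CohortSpec].
#' @examples
#' cohortSpec(nSubjects = 20, nRegions = 10, nTerritories = 3, seed = 1)
#' @export
cohortSpec <- function(nSubjects = 180L, nRegions = 116L,
                       territoryPartition = integer(0), nTerritories = 12L,
                       withinTerritorySpread = 0.8,
                       lesionSize = list(type = "lognormal",
                                         medianVoxels = 150, sdlog = 0.7),
                       seed = 1L) {
  new("CohortSpec",
      nSubjects = checkCount(nSubjects, "nSubjects"),
      nRegions = checkCount(nRegions, "nRegions"),
      territoryPartition = as.integer(territoryPartition),
      nTerritories = checkCount(nTerritories, "nTerritories"),
      withinTerritorySpread = checkProb(withinTerritorySpread,
                                        "withinTerritorySpread"),
      lesionSize = lesionSize,
      seed = checkSeed(seed))
}

#' Construct a lesion-load matrix
#'
#' Builds a [LoadMatrix] from a subjects x regions matrix of lesion-load
#' proportions, computing the unbiased per-region sample SDs.
#'
#' @param values numeric matrix with entries in \[0,1\].
#' @param regionIds integer region identifiers (defaults to 1..ncol).
#' @param subjectIds character subject identifiers (defaults to S001..).
#' @return A [LoadMatrix].
#' @export
newLoadMatrix <- function(values, regionIds = seq_len(ncol(values)),
                          subjectIds = NULL) {
  values <- as.matrix(values)
  regionIds <- as.integer(regionIds)
  if (is.null(subjectIds)) {
    subjectIds <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("S%03d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(subjectIds, sprintf("region_%d", regionIds))
  sds <- if (nrow(values) > 1L) apply(values, 2L, sd) else rep(0, ncol(values))
  new("LoadMatrix", values = values, regionIds = regionIds,
      perRegionSd = setNames(as.numeric(sds), colnames(values)))
}

#' Construct a stability-run configuration
#'
#' Defaults follow the study design: 100 repetitions, each drawing a random
#' subsample of 120 of the 180 subjects (two-thirds), mapping with both the
#' univariate and the lasso mapper, 5-fold cross-validation for the lasso
#' penalty, and family-wise alpha 0.05 for the univariate mapper.
#'
#' @param nReps number of subsampling repetitions.
#' @param subsampleSize subjects drawn (without replacement) per repetition.
#' @param mappers character subset of `c("univariate", "lasso")`.
#' @param reportThreshold minimum occurrence count for the stability report.
#' @param masterSeed master RNG seed.
#' @param alpha family-wise significance level for the univariate mapper.
#' @param lassoFolds cross-validation folds.
#' @param lassoGridSize penalty grid size.
#' @param lassoRule `"1se"` (largest penalty within one SE of the CV minimum,
#'   default) or `"min"` (exact CV-MSE minimizer).
#' @return A [StabilityConfig].
#' @examples
#' stabilityConfig(nReps = 10, subsampleSize = 30, masterSeed = 7)
#' @export
stabilityConfig <- function(nReps = 100L, subsampleSize = 120L,
                            mappers = c("univariate", "lasso"),
                            reportThreshold = 10L, masterSeed = 1L,
                            alpha = 0.05, lassoFolds = 5L,
                            lassoGridSize = 100L,
                            lassoRule = c("1se", "min")) {
  lassoRule <- match.arg(lassoRule)
  new("StabilityConfig",
      nReps = checkCount(nReps, "nReps"),
      subsampleSize = checkCount(subsampleSize, "subsampleSize"),
      mappers = as.character(mappers),
      reportThreshold = checkCount(reportThreshold, "reportThreshold", min = 0L),
      masterSeed = checkSeed(masterSeed),
      alpha = as.numeric(alpha),
      lassoFolds = checkCount(lassoFolds, "lassoFolds", min = 2L),
      lassoGridSize = checkCount(lassoGridSize, "lassoGridSize", min = 2L),
      lassoRule = lassoRule)
}
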