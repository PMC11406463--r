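#' AtlasVolume: an integer-labelled 3-D parcellation
#'
#' A 3-D volume whose voxels carry integer region labels: 0 is background,
#' 1..R are region identifiers. Regions are spatially contiguous and
#' non-overlapping, emulating an anatomical atlas parcellation such as the
#' 116-region AAL whole-brain atlas.
#'
#' @slot labels 3-D integer array of voxel labels (0 = background).
#' @slot regionIds ordered integer vector of the R distinct non-zero labels,
#'   consecutive from 1.
#'
#' @seealso [generateAtlas()], [extractRegionLoads()]
#' @export
setClass("AtlasVolume",
  representation(labels = "array", regionIds = "integer"))

setValidity("AtlasVolume", function(object) {
  lab <- object@labels
  if (length(dim(lab)) != 3L) return("labels must be a 3-D array")
  if (!is.integer(lab)) return("labels must be an integer array")
  ids <- object@regionIds
  R <- length(ids)
  if (R < 1L) return("at least one region is required")
  if (!identical(ids, seq_len(R))) {
    return("regionIds must be consecutive integers starting at 1")
  }
  present <- sort(unique(as.vector(lab)))
  if (!all(present %in% c(0L, ids))) {
    return("labels contain values outside {0} ∪ regionIds")
  }
  if (!all(ids %in% present)) return("every region must occupy at least 1 voxel")
  TRUE
})

#' CohortSpec: parameters of a synthetic lesion cohort
#'
#' Describes how a synthetic cohort of lesioned subjects is generated:
#' cohort size, atlas region count, the grouping of regions into
#' vascular-territory-like clusters, the lesion extent distribution, and the
#' probability that a growing lesion spills into neighbouring regions of the
#' same territory (the multicollinearity knob).
#'
#' @slot nSubjects number of subjects (study setting: 180).
#' @slot nRegions number of atlas regions (study setting: 116).
#' @slot territoryPartition integer vector assigning each region to a
#'   territory; `integer(0)` means "derive from the atlas geometry with
#'   `nTerritories` clusters".
#' @slot nTerritories number of territory clusters used when
#'   `territoryPartition` is empty.
#' @slot withinTerritorySpread probability in \[0,1\] that lesion growth
#'   crosses into an adjacent region of the same territory.
#' @slot lesionSize list describing the lesion extent distribution; either
#'   `list(type = "fixed", size = <voxels>)` or
#'   `list(type = "lognormal", medianVoxels = <voxels>, sdlog = <..>)`.
#' @slot seed RNG seed making the cohort fully reproducible.
#'
#' @seealso [cohortSpec()], [generateLesionMasks()]
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", nRegions = "integer",
                 territoryPartition = "integer", nTerritories = "integer",
                 withinTerritorySpread = "numeric", lesionSize = "list",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  if (object@nRegions < 1L) return("nRegions must be >= 1")
  tp <- object@territoryPartition
  if (length(tp) > 0L) {
    if (length(tp) != object@nRegions) {
      return("territoryPartition must have one entry per region")
    }
    if (anyNA(tp) || any(tp < 1L)) return("territory labels must be positive")
  } else if (object@nTerritories < 1L) {
    return("nTerritories must be >= 1")
  }
  s <- object@withinTerritorySpread
  if (!is.finite(s) || s < 0 || s > 1) {
    return("withinTerritorySpread must be in [0, 1]")
  }
  ls <- object@lesionSize
  if (is.null(ls$type) || !ls$type %in% c("fixed", "lognormal")) {
    return("lesionSize$type must be 'fixed' or 'lognormal'")
  }
  if (ls$type == "fixed" && (is.null(ls$size) || ls$size < 0)) {
    return("fixed lesionSize needs a non-negative 'size'")
  }
  if (ls$type == "lognormal" &&
      (is.null(ls$medianVoxels) || ls$medianVoxels <= 0 ||
       is.null(ls$sdlog) || ls$sdlog < 0)) {
    return("lognormal lesionSize needs positive 'medianVoxels' and 'sdlog' >= 0")
  }
  TRUE
})

#' LesionCohort: per-subject lesion masks and/or derived region loads
#'
#' Holds the cohort-level lesion data: optionally one binary 3-D mask per
#' subject (aligned to an [AtlasVolume]) and/or the derived subjects x regions
#' lesion-load matrix with entries in \[0,1\].
#'
#' @slot subjectIds character vector of subject identifiers.
#' @slot masks list of 3-D binary integer arrays (may be empty).
#' @slot loads numeric matrix of lesion-load proportions, subjects x regions
#'   (may be 0 x 0 when only masks are present).
#' @slot metadata list of provenance details (generator spec, territories).
#'
#' @seealso [generateLesionMasks()], [extractRegionLoads()]
#' @export
setClass("LesionCohort",
  representation(subjectIds = "character", masks = "list",
                 loads = "matrix", metadata = "list"))

setValidity("LesionCohort", function(object) {
  n <- length(object@subjectIds)
  hasMasks <- length(object@masks) > 0L
  hasLoads <- length(object@loads) > 0L
  if (!hasMasks && !hasLoads) return("at least one of masks/loads must be present")
  if (hasMasks && length(object@masks) != n) {
    return("number of masks must equal number of subjects")
  }
  if (hasLoads) {
    if (nrow(object@loads) != n) return("loads must have one row per subject")
    v <- object@loads
    if (anyNA(v) || any(v < 0) || any(v > 1)) return("loads must lie in [0, 1]")
  }
  TRUE
})

#' LoadMatrix: subjects x regions lesion-load feature matrix
#'
#' The feature set X of a lesion-deficit analysis: for each subject and atlas
#' region, the proportion of the region's voxels that the subject's lesion
#' overlaps. Carries the per-region sample standard deviations used to
#' calibrate simulated deficit noise.
#'
#' @slot values numeric matrix of proportions in \[0,1\], one row per subject,
#'   one column per region (dimnames = subject / region ids).
#' @slot regionIds integer vector of region identifiers (column order).
#' @slot perRegionSd numeric vector of unbiased (n-1 denominator) sample SDs
#'   of each region's loads.
#'
#' @seealso [extractRegionLoads()], [simulateDeficit()]
#' @export
setClass("LoadMatrix",
  representation(values = "matrix", regionIds = "integer",
                 perRegionSd = "numeric"))

setValidity("LoadMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(v < 0) || any(v > 1)) return("values must lie in [0, 1]")
  if (length(object@regionIds) != ncol(v)) {
    return("regionIds must have one entry per column")
  }
  sds <- object@perRegionSd
  if (length(sds) != ncol(v)) return("perRegionSd must have one entry per column")
  if (any(sds < 0)) return("perRegionSd must be non-negative")
  colSd <- apply(v, 2L, sd)
  if (nrow(v) > 1L && !isTRUE(all.equal(as.numeric(colSd), as.numeric(sds),
                                        tolerance = 1e-8))) {
    return("perRegionSd does not match the sample SD of values")
  }
  TRUE
})

#' DeficitVector: one continuous behavioural score per subject
#'
#' The response y of a lesion-deficit analysis: a simulated (or measured)
#' continuous deficit score for every subject, with the provenance of the
#' simulation recorded.
#'
#' @slot scores numeric vector, one finite value per subject.
#' @slot provenance list describing how the scores arose (target region or
#'   weight vector, noise multiplier, seed) or `list(source = "measured")`.
#'
#' @seealso [simulateDeficit()]
#' @export
setClass("DeficitVector",
  representation(scores = "numeric", provenance = "list"))

setValidity("DeficitVector", function(object) {
  if (length(object@scores) < 1L) return("scores must be non-empty")
  if (!all(is.finite(object@scores))) return("scores must all be finite")
  TRUE
})

#' StabilityConfig: parameters of the subsample-and-map procedure
#'
#' @slot nReps number of subsampling repetitions (study setting: 100).
#' @slot subsampleSize subjects drawn without replacement per repetition
#'   (study setting: 120 of 180, i.e. two-thirds).
#' @slot mappers character subset of `c("univariate", "lasso")`.
#' @slot reportThreshold minimum occurrence count for a region to enter the
#'   stability report (typically 10 or 25 of 100 repetitions).
#' @slot masterSeed master RNG seed; repetition i uses child seed
#'   `masterSeed XOR i`.
#' @slot alpha family-wise significance level of the univariate mapper.
#' @slot lassoFolds number of cross-validation folds (study setting: 5).
#' @slot lassoGridSize number of penalty values on the log-spaced grid.
#' @slot lassoRule penalty selection rule, `"min"` or `"1se"`.
#'
#' @seealso [stabilityConfig()], [runStability()]
#' @export
setClass("StabilityConfig",
  representation(nReps = "integer", subsampleSize = "integer",
                 mappers = "character", reportThreshold = "integer",
                 masterSeed = "integer", alpha = "numeric",
                 lassoFolds = "integer", lassoGridSize = "integer",
                 lassoRule = "character"))

setValidity("StabilityConfig", function(object) {
  if (object@nReps < 1L) return("nReps must be >= 1")
  if (object@subsampleSize < 1L) return("subsampleSize must be >= 1")
  if (length(object@mappers) < 1L ||
      !all(object@mappers %in% c("univariate", "lasso"))) {
    return("mappers must be a non-empty subset of {'univariate', 'lasso'}")
  }
  if (object@reportThreshold < 0L || object@reportThreshold > object@nReps) {
    return("reportThreshold must lie in 0..nReps")
  }
  if (!is.finite(object@alpha) || object@alpha <= 0 || object@alpha >= 1) {
    return("alpha must lie in (0, 1)")
  }
  if (object@lassoFolds < 2L) return("lassoFolds must be >= 2")
  if (object@lassoGridSize < 2L) return("lassoGridSize must be >= 2")
  if (!object@lassoRule %in% c("min", "1se")) {
    return("lassoRule must be 'min' or '1se'")
  }
  TRUE
})

#' StabilityTable: per-region occurrence counts over subsampling repetitions
#'
#' The outcome of the stability pipeline: for each configured mapper, the full
#' repetitions x regions boolean selection matrix, from which per-region
#' occurrence counts (the study's outcome measure) are derived.
#'
#' @slot selections named list (one entry per mapper) of nReps x R logical
#'   matrices; entry \[i, r\] is TRUE when repetition i implicated region r.
#' @slot regionIds integer vector of region identifiers (column order).
#' @slot nReps number of repetitions.
#' @slot subsampleSize subjects per repetition.
#' @slot masterSeed master seed used for the run.
#'
#' @seealso [runStability()], [occurrenceCounts()], [summarizeStability()]
#' @export
setClass("StabilityTable",
  representation(selections = "list", regionIds = "integer",
                 nReps = "integer", subsampleSize = "integer",
                 masterSeed = "integer"))

setValidity("StabilityTable", function(object) {
  if (length(object@selections) < 1L) return("selections must be non-empty")
  if (is.null(names(object@selections)) || any(names(object@selections) == "")) {
    return("selections must be named by mapper")
  }
  R <- length(object@regionIds)
  for (m in names(object@selections)) {
    S <- object@selections[[m]]
    if (!is.matrix(S) || !is.logical(S)) {
      return(sprintf("selections[['%s']] must be a logical matrix", m))
    }
    if (nrow(S) != object@nReps || ncol(S) != R) {
      return(sprintf("selections[['%s']] must be nReps x R", m))
    }
  }
  TRUE
})
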