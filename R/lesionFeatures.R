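## Region lesion-load extraction and disk I/O for masks, atlases and load
## matrices. NIfTI handling is delegated to RNifti; the affine is used only to
## check grid compatibility, never to resample.

#' Extract the subjects x regions lesion-load matrix
#'
#' For every subject and atlas region, computes the proportion of the region's
#' voxels overlapped by the subject's lesion:
#' `values[s, r] = |mask_s ∩ region_r| / |region_r|`. The denominator is the
#' total atlas voxel count of the region. Per-region sample SDs use the
#' unbiased (n-1) estimator.
#'
#' @param cohort a [LesionCohort] with masks present.
#' @param atlas the [AtlasVolume] the masks are aligned to.
#' @return A [LoadMatrix].
#' @examples
#' atlas <- generateAtlas(c(10, 10, 10), nRegions = 4, seed = 1)
#' spec <- cohortSpec(nSubjects = 5, nRegions = 4, nTerritories = 2,
#'                    lesionSize = list(type = "fixed", size = 10), seed = 3)
#' loads <- extractRegionLoads(generateLesionMasks(atlas, spec), atlas)
#' @export
extractRegionLoads <- function(cohort, atlas) {
  stopifnot(is(cohort, "LesionCohort"), is(atlas, "AtlasVolume"))
  masks <- cohort@masks
  if (!length(masks)) stop("cohort carries no masks", call. = FALSE)
  shape <- dim(atlas@labels)
  R <- length(atlas@regionIds)
  regionSize <- tabulate(atlas@labels[atlas@labels > 0L], nbins = R)
  if (any(regionSize == 0L)) {
    stop("atlas contains a zero-voxel region", call. = FALSE)
  }
  loads <- matrix(0, length(masks), R)
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    if (!identical(dim(m), shape)) {
      stop(sprintf("mask %d has dimensions %s but the atlas is %s",
                   s, paste(dim(m), collapse = "x"),
                   paste(shape, collapse = "x")), call. = FALSE)
    }
    vals <- unique(as.vector(m))
    if (!all(vals %in% c(0, 1))) {
      stop(sprintf("mask %d is not binary", s), call. = FALSE)
    }
    lesioned <- atlas@labels[m == 1]
    loads[s, ] <- tabulate(lesioned[lesioned > 0L], nbins = R) / regionSize
  }
  newLoadMatrix(loads, regionIds = atlas@regionIds,
                subjectIds = cohort@subjectIds)
}

#' Write a cohort and its atlas as NIfTI volumes
#'
#' @param cohort a [LesionCohort] with masks.
#' @param atlas the matching [AtlasVolume].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the atlas path and the mask paths (one
#'   `mask_<subjectId>.nii.gz` per subject).
#' @export
writeCohortNifti <- function(cohort, atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atlasPath <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(atlas@labels, atlasPath)
  maskPaths <- vapply(seq_along(cohort@subjectIds), function(s) {
    p <- file.path(dir, sprintf("mask_%s.nii.gz", cohort@subjectIds[s]))
    RNifti::writeNifti(cohort@masks[[s]], p)
    p
  }, character(1))
  invisible(list(atlas = atlasPath, masks = maskPaths))
}

#' Read lesion masks and an atlas from NIfTI files
#'
#' Masks are binarized at 0.5 (values > 0.5 become 1), tolerating
#' interpolation artefacts in float-stored masks. All volumes must share the
#' atlas grid; affines are compared for grid compatibility only (no
#' resampling).
#'
#' @param maskPaths character vector of NIfTI mask paths; subject order
#'   follows this list.
#' @param atlasPath path to the integer-labelled NIfTI atlas.
#' @param affineTol maximum absolute elementwise deviation tolerated between
#'   mask and atlas affines.
#' @return A list with elements `cohort` (a [LesionCohort], masks only) and
#'   `atlas` (an [AtlasVolume]).
#' @export
loadCohortFromDisk <- function(maskPaths, atlasPath, affineTol = 1e-4) {
  atlasImg <- RNifti::readNifti(atlasPath)
  labels <- array(as.integer(round(as.vector(atlasImg))), dim = dim(atlasImg))
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids) || !identical(ids, seq_along(ids))) {
    stop("atlas labels must be consecutive integers starting at 1", call. = FALSE)
  }
  atlas <- new("AtlasVolume", labels = labels, regionIds = ids)
  atlasXform <- RNifti::xform(atlasImg)
  masks <- vector("list", length(maskPaths))
  for (s in seq_along(maskPaths)) {
    img <- RNifti::readNifti(maskPaths[s])
    if (!identical(dim(img), dim(labels))) {
      stop(sprintf("mask '%s' grid %s does not match atlas grid %s",
                   maskPaths[s], paste(dim(img), collapse = "x"),
                   paste(dim(labels), collapse = "x")), call. = FALSE)
    }
    if (max(abs(RNifti::xform(img) - atlasXform)) > affineTol) {
      stop(sprintf("mask '%s' affine deviates from the atlas affine beyond tolerance",
                   maskPaths[s]), call. = FALSE)
    }
    masks[[s]] <- array(as.integer(as.vector(img) > 0.5), dim = dim(labels))
  }
  subjectIds <- sub("\\.nii(\\.gz)?$", "", basename(maskPaths))
  subjectIds <- sub("^mask_", "", subjectIds)
  cohort <- new("LesionCohort", subjectIds = subjectIds, masks = masks,
                loads = matrix(numeric(0), 0, 0), metadata = list())
  list(cohort = cohort, atlas = atlas)
}

#' Write / read a lesion-load matrix as CSV
#'
#' The CSV has a `subject_id` column followed by one `region_<id>` column per
#' region, one row per subject.
#'
#' @param loads a [LoadMatrix].
#' @param path output CSV path.
#' @return `writeLoadMatrixCsv`: the path, invisibly. `readLoadMatrixCsv`:
#'   a [LoadMatrix].
#' @export
writeLoadMatrixCsv <- function(loads, path) {
  stopifnot(is(loads, "LoadMatrix"))
  df <- data.frame(subject_id = subjectIds(loads), loads@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLoadMatrixCsv
#' @export
readLoadMatrixCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("load-matrix CSV must have a 'subject_id' column", call. = FALSE)
  }
  regionCols <- setdiff(names(df), "subject_id")
  ids <- as.integer(sub("^region_", "", regionCols))
  if (anyNA(ids)) stop("region columns must be named 'region_<id>'", call. = FALSE)
  newLoadMatrix(as.matrix(df[regionCols]), regionIds = ids,
                subjectIds = as.character(df$subject_id))
}

#' Write / read a deficit vector as CSV
#'
#' Two columns: `subject_id`, `score`.
#'
#' @param deficit a [DeficitVector] (or numeric vector).
#' @param subjectIds subject identifiers used when `deficit` is unnamed.
#' @param path CSV path.
#' @return `writeDeficitCsv`: the path, invisibly. `readDeficitCsv`: a
#'   [DeficitVector] with provenance `"measured"`.
#' @export
writeDeficitCsv <- function(deficit, path, subjectIds = NULL) {
  y <- asScores(deficit)
  ids <- if (!is.null(subjectIds)) subjectIds
         else if (!is.null(names(y))) names(y)
         else sprintf("S%03d", seq_along(y))
  write.csv(data.frame(subject_id = ids, score = unname(y)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeDeficitCsv
#' @export
readDeficitCsv <- function(path) {
  df <- read.csv(path)
  if (!all(c("subject_id", "score") %in% names(df))) {
    stop("deficit CSV must have 'subject_id' and 'score' columns", call. = FALSE)
  }
  new("DeficitVector",
      scores = setNames(as.numeric(df$score), as.character(df$subject_id)),
      provenance = list(source = "measured"))
}
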