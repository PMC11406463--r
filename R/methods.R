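## Accessor and show methods for the S4 containers.

#' @rdname lesionstab-accessors
#' @export
setMethod("regionIds", "AtlasVolume", function(x) x@regionIds)

#' @rdname lesionstab-accessors
#' @export
setMethod("regionIds", "LoadMatrix", function(x) x@regionIds)

#' @rdname lesionstab-accessors
#' @export
setMethod("regionIds", "StabilityTable", function(x) x@regionIds)

#' @rdname lesionstab-accessors
#' @export
setMethod("subjectIds", "LesionCohort", function(x) x@subjectIds)

#' @rdname lesionstab-accessors
#' @export
setMethod("subjectIds", "LoadMatrix", function(x) rownames(x@values))

#' @rdname lesionstab-accessors
#' @export
setMethod("atlasLabels", "AtlasVolume", function(x) x@labels)

#' @rdname lesionstab-accessors
#' @export
setMethod("lesionMasks", "LesionCohort", function(x) x@masks)

#' @rdname lesionstab-accessors
#' @export
setMethod("loadValues", "LesionCohort", function(x) x@loads)

#' @rdname lesionstab-accessors
#' @export
setMethod("loadValues", "LoadMatrix", function(x) x@values)

#' @rdname lesionstab-accessors
#' @export
setMethod("perRegionSd", "LoadMatrix", function(x) x@perRegionSd)

#' @rdname lesionstab-accessors
#' @export
setMethod("deficitScores", "DeficitVector", function(x) x@scores)

#' @rdname lesionstab-accessors
#' @export
setMethod("selectionMatrix", "StabilityTable", function(x, mapper = NULL) {
  if (is.null(mapper)) return(x@selections)
  if (!mapper %in% names(x@selections)) {
    stop(sprintf("no selections recorded for mapper '%s'", mapper), call. = FALSE)
  }
  x@selections[[mapper]]
})

#' @rdname lesionstab-accessors
#' @export
setMethod("occurrenceCounts", "StabilityTable", function(x, mapper = NULL) {
  if (is.null(mapper)) {
    return(lapply(x@selections, function(S) {
      setNames(as.integer(colSums(S)), colnames(S))
    }))
  }
  S <- selectionMatrix(x, mapper)
  setNames(as.integer(colSums(S)), colnames(S))
})

#' Subset a LoadMatrix by subject and/or region
#'
#' Row subsetting (subjects) recomputes the per-region sample SDs on the
#' subset, so noise calibration and mapper preconditions always refer to the
#' cohort actually analysed.
#'
#' @param x a [LoadMatrix].
#' @param i subject (row) index.
#' @param j region (column) index.
#' @param ... ignored.
#' @param drop ignored; the result is always a LoadMatrix.
#' @return A [LoadMatrix].
#' @export
setMethod("[", "LoadMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  newLoadMatrix(x@values[i, j, drop = FALSE], regionIds = x@regionIds[j])
})

setMethod("show", "AtlasVolume", function(object) {
  cat(sprintf("AtlasVolume: %s grid, %d regions, %d foreground voxels\n",
              paste(dim(object@labels), collapse = " x "),
              length(object@regionIds), sum(object@labels > 0L)))
})

setMethod("show", "CohortSpec", function(object) {
  terr <- if (length(object@territoryPartition)) {
    sprintf("%d territories (explicit)", length(unique(object@territoryPartition)))
  } else {
    sprintf("%d territories (derived)", object@nTerritories)
  }
  cat(sprintf(paste0("CohortSpec: %d subjects, %d regions, %s,\n",
                     "  within-territory spread %.2f, lesion size %s, seed %d\n"),
              object@nSubjects, object@nRegions, terr,
              object@withinTerritorySpread,
              if (object@lesionSize$type == "fixed") {
                sprintf("fixed %d voxels", as.integer(object@lesionSize$size))
              } else {
                sprintf("lognormal (median %g voxels, sdlog %g)",
                        object@lesionSize$medianVoxels, object@lesionSize$sdlog)
              },
              object@seed))
})

setMethod("show", "LesionCohort", function(object) {
  cat(sprintf("LesionCohort: %d subjects, masks: %s, load matrix: %s\n",
              length(object@subjectIds),
              if (length(object@masks)) "yes" else "no",
              if (length(object@loads)) {
                sprintf("%d x %d", nrow(object@loads), ncol(object@loads))
              } else "no"))
})

setMethod("show", "LoadMatrix", function(object) {
  cat(sprintf("LoadMatrix: %d subjects x %d regions, mean load %.4f, %d constant region(s)\n",
              nrow(object@values), ncol(object@values), mean(object@values),
              sum(object@perRegionSd == 0)))
})

setMethod("show", "DeficitVector", function(object) {
  src <- object@provenance
  what <- if (!is.null(src$region)) {
    sprintf("single-region target %d, noise k = %g", src$region, src$noiseK)
  } else if (!is.null(src$weights)) {
    sprintf("%d-region weighted target, noise k = %g",
            sum(src$weights > 0), src$noiseK)
  } else "measured"
  cat(sprintf("DeficitVector: %d subjects, %s\n", length(object@scores), what))
})

setMethod("show", "StabilityConfig", function(object) {
  cat(sprintf(paste0("StabilityConfig: %d reps of %d subjects, mappers: %s,\n",
                     "  report threshold %d, master seed %d\n"),
              object@nReps, object@subsampleSize,
              paste(object@mappers, collapse = ", "),
              object@reportThreshold, object@masterSeed))
})

setMethod("show", "StabilityTable", function(object) {
  cat(sprintf("StabilityTable: %d repetitions x %d regions\n",
              object@nReps, length(object@regionIds)))
  for (m in names(object@selections)) {
    cnt <- colSums(object@selections[[m]])
    cat(sprintf("  %-10s selected %.2f regions/rep; %d region(s) ever selected\n",
                m, mean(rowSums(object@selections[[m]])), sum(cnt > 0)))
  }
})
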