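#' @name lesionstab-accessors
#' @title Accessors for lesionstab data classes
#'
#' @description Slot access for the package's S4 containers: region and
#' subject identifiers, atlas labels, lesion masks, the lesion-load matrix and
#' its per-region standard deviations, deficit scores, and the selection
#' matrices / occurrence counts of a stability run.
#'
#' @param x an object of the documented class.
#' @param mapper for [StabilityTable] accessors: mapper name; `NULL` returns
#'   all mappers.
#' @return The requested component; see the individual methods.
NULL

#' @rdname lesionstab-accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("lesionMasks", function(x) standardGeneric("lesionMasks"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("loadValues", function(x) standardGeneric("loadValues"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("perRegionSd", function(x) standardGeneric("perRegionSd"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("deficitScores", function(x) standardGeneric("deficitScores"))

#' @rdname lesionstab-accessors
#' @export
setGeneric("selectionMatrix", function(x, mapper = NULL) {
  standardGeneric("selectionMatrix")
})

#' @rdname lesionstab-accessors
#' @export
setGeneric("occurrenceCounts", function(x, mapper = NULL) {
  standardGeneric("occurrenceCounts")
})
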