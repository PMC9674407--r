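#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor layer so code never reaches into slots directly.
#'
#' @param x An object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("textLength", function(x) standardGeneric("textLength"))

#' @rdname accessors
#' @export
setGeneric("suffixArray", function(x) standardGeneric("suffixArray"))

#' @rdname accessors
#' @export
setGeneric("bwtRuns", function(x) standardGeneric("bwtRuns"))

#' @rdname accessors
#' @export
setGeneric("hapCount", function(x) standardGeneric("hapCount"))

#' @rdname accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("editTable", function(x) standardGeneric("editTable"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname accessors
#' @export
setGeneric("numRuns", function(x) standardGeneric("numRuns"))

#' @rdname accessors
#' @export
setGeneric("evidenceCounts", function(x) standardGeneric("evidenceCounts"))

setMethod("textLength", "MarkerPanel", function(x) length(x@text))
setMethod("textLength", "FMIndex", function(x) x@n)
setMethod("textLength", "PanelIndex", function(x) x@fm@n)
setMethod("suffixArray", "FMIndex", function(x) x@sa)
setMethod("suffixArray", "PanelIndex", function(x) x@fm@sa)
setMethod("bwtRuns", "FMIndex", function(x) x@runCount)
setMethod("bwtRuns", "PanelIndex", function(x) x@fm@runCount)
setMethod("hapCount", "MarkerPanel", function(x) x@hapCount)
setMethod("hapCount", "PanelIndex", function(x) x@panel@hapCount)
setMethod("markerTable", "MarkerPanel", function(x) x@markers)
setMethod("markerTable", "PanelIndex", function(x) x@panel@markers)
setMethod("editTable", "MarkerPanel", function(x) x@edits)
setMethod("editTable", "PanelIndex", function(x) x@panel@edits)
setMethod("siteTable", "MarkerPanel", function(x) x@sites)
setMethod("siteTable", "PanelIndex", function(x) x@panel@sites)
setMethod("windowSize", "SmearedMarkerArray", function(x) x@window)
setMethod("windowSize", "PanelIndex", function(x) x@window)
setMethod("numRuns", "SmearedMarkerArray", function(x) x@numRuns)
setMethod("numRuns", "PanelIndex", function(x) x@markerIndex@numRuns)
setMethod("evidenceCounts", "EvidenceTable", function(x) x@counts)
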