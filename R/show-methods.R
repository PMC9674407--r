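#' @describeIn MarkerPanel-class Compact summary.
#' @param object Object to display.
#' @export
setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel:", length(object@text), "bp text,",
        object@hapCount, "haplotypes (incl. T_0),",
        length(object@refNames), "chromosome(s)\n")
    cat("  markers:", nrow(object@markers), "at",
        sum(object@sites$marked), "marked site(s) of",
        nrow(object@sites), "; edits:", nrow(object@edits),
        "; minAf:", object@minAf, "\n")
})

#' @describeIn FMIndex-class Compact summary.
#' @param object Object to display.
#' @export
setMethod("show", "FMIndex", function(object) {
    cat("FMIndex: n =", object@n, ", BWT runs r =", object@runCount,
        if (object@sampleRate > 0L)
            paste0(", SA sample rate s = ", object@sampleRate)
        else ", no SA sample", "\n")
})

#' @describeIn SmearedMarkerArray-class Compact summary.
#' @param object Object to display.
#' @export
setMethod("show", "SmearedMarkerArray", function(object) {
    cat("SmearedMarkerArray: w =", object@window, ", rows =", object@n,
        ", runs =", object@numRuns, ", payload =", nrow(object@payload),
        "marker(s), ~", markerIndexSize(object), "bytes\n")
})

#' @describeIn PanelIndex-class Compact summary.
#' @param object Object to display.
#' @export
setMethod("show", "PanelIndex", function(object) {
    cat("PanelIndex (w =", object@window, ")\n")
    methods::show(object@panel)
    methods::show(object@fm)
    methods::show(object@markerIndex)
})

#' @describeIn EvidenceTable-class Compact summary.
#' @param object Object to display.
#' @export
setMethod("show", "EvidenceTable", function(object) {
    nSites <- length(unique(paste(object@counts$chrom,
                                  object@counts$refOffset)))
    cat("EvidenceTable:", sum(object@counts$count), "observation(s) at",
        nSites, "site(s) from", object@nReads, "read(s),",
        object@nExtensions, "extension(s)\n")
})
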