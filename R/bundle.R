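## Index bundle: one-call construction from FASTA + VCF, and versioned
## serialization.

.BUNDLE_VERSION <- 1L

#' Build a complete genotyping index from a reference and a phased VCF
#'
#' Convenience constructor running [loadReference()] (if given a path),
#' [buildPanel()], [buildFMIndex()] and [buildMarkerIndex()], and attaching
#' the suffix-rank-ordered unsmeared marker array used by the exact FL and
#' locate query strategies.
#'
#' @param reference Path to a FASTA file, or a named character vector /
#'   `DNAStringSet` of chromosomes.
#' @param vcfPath Path to a sorted, phased multi-sample VCF.
#' @param window Smearing window `w` (default 19).
#' @param minAf Minor-allele-frequency threshold; sites with minor-allele
#'   frequency `<= minAf` are not marked (default 0).
#' @param saSampleRate Suffix-array sampling rate for locate queries
#'   (default 16; 0 disables).
#' @param excludeSamples Samples to hold out of the panel.
#' @return A [PanelIndex-class].
#' @export
buildPanelIndex <- function(reference, vcfPath, window = 19L, minAf = 0,
                            saSampleRate = 16L,
                            excludeSamples = character(0)) {
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference) && is.null(names(reference)))
        reference <- loadReference(reference)
    panel <- buildPanel(reference, vcfPath, minAf = minAf,
                        excludeSamples = excludeSamples)
    fm <- buildFMIndex(panel@text, saSampleRate = saSampleRate)
    arr <- buildMarkerIndex(panel, fm, window = window)
    methods::new("PanelIndex", panel = panel, fm = fm, markerIndex = arr,
                 maRows = permuteMarkers(panel, fm),
                 window = as.integer(window))
}

#' Save a panel index bundle
#'
#' Serialises the bundle with a format version stamp; [loadPanelIndex()]
#' refuses bundles written by an incompatible version.
#'
#' @param index A [PanelIndex-class].
#' @param path Output file path (conventionally `.mai`).
#' @return Invisibly, `path`.
#' @export
savePanelIndex <- function(index, path) {
    stopifnot(methods::is(index, "PanelIndex"))
    saveRDS(list(format = "markerArray-index", version = .BUNDLE_VERSION,
                 index = index), path)
    invisible(path)
}

#' Load a panel index bundle
#'
#' @param path File written by [savePanelIndex()].
#' @return A [PanelIndex-class].
#' @export
loadPanelIndex <- function(path) {
    x <- readRDS(path)
    if (!is.list(x) || !identical(x$format, "markerArray-index"))
        stop("not a markerArray index bundle: ", path)
    if (!identical(x$version, .BUNDLE_VERSION))
        stop("index bundle version ", x$version,
             " is not supported by this build (expected ", .BUNDLE_VERSION,
             ")")
    methods::validObject(x$index@panel)
    x$index
}
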