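#' @import methods
NULL

## ---------------------------------------------------------------------------
## MarkerPanel: the concatenated pangenome text plus markers and edits
## ---------------------------------------------------------------------------

#' MarkerPanel: a concatenated haplotype panel with dense markers
#'
#' Holds the pangenome text \eqn{T = T_0 \cdot T_1 \cdots T_n} (reference
#' first, then one sequence per phased haplotype, each terminated by a
#' separator symbol, the whole text by a unique sentinel), the dense marker
#' array \eqn{M} (one record per haplotype per polymorphic column passing the
#' allele-frequency filter), the edit table \eqn{E}, and the per-site
#' REF/ALT strings needed to write VCF output.
#'
#' @slot text Integer vector; the panel text in internal symbol codes.
#' @slot hapNames Character; haplotype names, reference (`T_0`) first.
#' @slot hapStart Integer; 0-based text offset of each haplotype's first base.
#' @slot hapLen Integer; DNA length of each haplotype (separator excluded).
#' @slot hapCount Integer scalar \eqn{N_h}: haplotypes including `T_0`.
#' @slot markers `data.frame` with columns `textOffset` (0-based offset in
#'   `text`), `chrom` (0-based chromosome index in reference order),
#'   `refOffset` (0-based offset within the chromosome on `T_0` coordinates,
#'   stored as double since it may exceed 2^31), and `allele` (0 = reference,
#'   k >= 1 = k-th alternate), sorted by `textOffset`.
#' @slot edits `data.frame` of distinct edit operations: `id` (dense, from 1;
#'   0 is the implicit null operation and never stored), `type` (one of
#'   `"sub"`, `"ins"`, `"del"`), `value` (replacement/inserted string, or the
#'   deleted length as a string for `"del"`).
#' @slot sites Per-site metadata `data.frame`: `chrom`, `refOffset`, `ref`,
#'   `alts` (comma-joined ALT strings), `editIds` (comma-joined edit ids, one
#'   per ALT), `marked` (logical: passed the frequency filter), `type`.
#' @slot refNames Character; chromosome names in reference order.
#' @slot refLens Integer; chromosome lengths.
#' @slot minAf Numeric; the minor-allele-frequency threshold used.
#' @slot samples Character; sample names contributing haplotypes.
#' @export
setClass("MarkerPanel", representation(
    text = "integer",
    hapNames = "character",
    hapStart = "integer",
    hapLen = "integer",
    hapCount = "integer",
    markers = "data.frame",
    edits = "data.frame",
    sites = "data.frame",
    refNames = "character",
    refLens = "integer",
    minAf = "numeric",
    samples = "character"
))

setValidity("MarkerPanel", function(object) {
    msg <- character(0)
    n <- length(object@text)
    if (n == 0L || object@text[n] != .SENTINEL)
        msg <- c(msg, "text must end with the sentinel symbol")
    if (sum(object@text == .SENTINEL) != 1L)
        msg <- c(msg, "sentinel must be unique")
    if (length(object@hapNames) != object@hapCount)
        msg <- c(msg, "hapNames length must equal hapCount")
    if (length(object@hapStart) != length(object@hapLen))
        msg <- c(msg, "hapStart/hapLen length mismatch")
    m <- object@markers
    if (nrow(m)) {
        hi <- findInterval(m$textOffset, object@hapStart)
        inside <- hi >= 1L & m$textOffset < object@hapStart[hi] + object@hapLen[hi]
        if (!all(inside))
            msg <- c(msg, "markers must lie strictly inside a haplotype's DNA interval")
        if (any(m$allele < 0 | m$allele > 15L))
            msg <- c(msg, "marker allele must be in [0, 15]")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FMIndex
## ---------------------------------------------------------------------------

#' FMIndex: suffix array, BWT, C array and rank/select structures
#'
#' Exact string-index substrate over the internal integer alphabet. Rank
#' queries are answered from a full occurrence-count matrix and select
#' queries from per-symbol position lists; run-length statistics are kept
#' for size reporting. Rows and text offsets are 0-based throughout; suffix
#' array ranges are half-open `[lo, hi)`.
#'
#' @slot n Integer; text length.
#' @slot sa Integer; suffix array, 0-based text offsets, length `n`.
#' @slot bwt Integer; BWT symbol codes, length `n`.
#' @slot C Integer; `C[c]` = number of text symbols with code < `c`
#'   (length = alphabet size).
#' @slot occ Integer matrix `(n+1) x alphabet`; `occ[i+1, c]` = occurrences
#'   of `c` in `bwt[0..i)`.
#' @slot selectPos List of integer vectors; 1-based BWT positions of each
#'   symbol, for select queries (FL steps).
#' @slot runCount Integer; number of maximal same-symbol runs `r` in the BWT.
#' @slot sampleRate Integer; suffix-array sampling rate `s` (0 = no sample).
#' @slot sampVal Integer; length-`n` vector with `SA[row]` at rows whose SA
#'   value is a multiple of `s`, `NA` elsewhere.
#' @export
setClass("FMIndex", representation(
    n = "integer",
    sa = "integer",
    bwt = "integer",
    cArr = "integer",
    occ = "matrix",
    selectPos = "list",
    runCount = "integer",
    sampleRate = "integer",
    sampVal = "integer"
))

setValidity("FMIndex", function(object) {
    msg <- character(0)
    n <- object@n
    if (length(object@sa) != n) msg <- c(msg, "sa length != n")
    if (length(object@bwt) != n) msg <- c(msg, "bwt length != n")
    if (n > 0L && !setequal(range(object@sa), c(0L, n - 1L)) &&
        !(n == 1L && object@sa[1] == 0L))
        msg <- c(msg, "sa must be a permutation of [0, n)")
    if (nrow(object@occ) != n + 1L) msg <- c(msg, "occ must have n+1 rows")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SmearedMarkerArray
## ---------------------------------------------------------------------------

#' SmearedMarkerArray: run-length sparse encoding of MA^w
#'
#' The marker array in suffix-rank order (`MA[i] = M[SA[i]]`), smeared `w`
#' positions to the left so that a backward search that queries only every
#' `w` steps cannot skip a mark, and stored with the sparse run-length
#' encoding: bit vector `S` marks run starts, `E` marks run ends, `X` holds
#' one marker list per run, and `B` marks each run's first element within the
#' flattened payload. The bit vectors are stored as sorted positions of their
#' 1 bits; rank/select are answered from those positions.
#'
#' @slot window Integer; the smearing window `w` (a mark at text offset `p`
#'   is attached to rows whose suffix starts in `[p - w, p]`, clamped at the
#'   containing haplotype's start, i.e. decoded lists span `SA[i] .. SA[i]+w`).
#' @slot n Integer; number of BWT rows.
#' @slot startPos Integer; 0-based rows where a run starts (the 1s of `S`).
#' @slot endPos Integer; 0-based rows where a run ends (the 1s of `E`).
#' @slot payload `data.frame` of flattened marker lists (`chrom`,
#'   `refOffset`, `allele`), runs concatenated in order of appearance.
#' @slot listStart Integer; 0-based offsets into `payload` of each run's
#'   first element (the 1s of `B`).
#' @slot numRuns Integer; number of maximal runs `x`.
#' @export
setClass("SmearedMarkerArray", representation(
    window = "integer",
    n = "integer",
    startPos = "integer",
    endPos = "integer",
    payload = "data.frame",
    listStart = "integer",
    numRuns = "integer"
))

setValidity("SmearedMarkerArray", function(object) {
    msg <- character(0)
    x <- object@numRuns
    if (length(object@startPos) != x) msg <- c(msg, "popcount(S) must equal numRuns")
    if (length(object@endPos) != x) msg <- c(msg, "popcount(E) must equal numRuns")
    if (length(object@listStart) != x) msg <- c(msg, "popcount(B) must equal numRuns")
    if (x > 0L) {
        if (any(object@endPos < object@startPos))
            msg <- c(msg, "run end before run start")
        if (is.unsorted(object@startPos, strictly = TRUE))
            msg <- c(msg, "run starts must be strictly increasing")
        lens <- diff(c(object@listStart, nrow(object@payload)))
        if (any(lens < 1L))
            msg <- c(msg, "every payload list must have length >= 1")
        if (any(lens > object@window + 1L))
            msg <- c(msg, "payload lists may not exceed w + 1 markers")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PanelIndex: the full index bundle
## ---------------------------------------------------------------------------

#' PanelIndex: the complete genotyping index bundle
#'
#' Ties together the panel text and markers, the FM-index, the smeared
#' marker array, and the suffix-rank-ordered (unsmeared) marker table used
#' by the exact FL and locate query strategies.
#'
#' @slot panel A [MarkerPanel-class].
#' @slot fm An [FMIndex-class] over the panel text.
#' @slot markerIndex A [SmearedMarkerArray-class].
#' @slot maRows `data.frame` (`row`, `chrom`, `refOffset`, `allele`): the
#'   unsmeared marker array MA in suffix-rank order, for the FL oracle.
#' @slot window Integer; the smearing window used at build time.
#' @export
setClass("PanelIndex", representation(
    panel = "MarkerPanel",
    fm = "FMIndex",
    markerIndex = "SmearedMarkerArray",
    maRows = "data.frame",
    window = "integer"
))

## ---------------------------------------------------------------------------
## EvidenceTable
## ---------------------------------------------------------------------------

#' EvidenceTable: per-site allele observation counts
#'
#' Aggregated genotype evidence across reads: for each marked site (chrom,
#' refOffset) the number of times each allele (0 = reference) was observed
#' by a finalized extension. At a site, `l` is the reference count and `k`
#' the total count over all alleles.
#'
#' @slot counts `data.frame` with columns `chrom`, `refOffset`, `allele`,
#'   `count`.
#' @slot nReads Integer; number of reads processed.
#' @slot nExtensions Integer; number of finalized (surviving) extensions.
#' @export
setClass("EvidenceTable", representation(
    counts = "data.frame",
    nReads = "integer",
    nExtensions = "integer"
))

.emptyCounts <- function() {
    data.frame(chrom = integer(0), refOffset = numeric(0),
               allele = integer(0), count = integer(0))
}

#' Create an empty evidence table
#' @return An [EvidenceTable-class] with zero counts.
#' @export
emptyEvidenceTable <- function() {
    new("EvidenceTable", counts = .emptyCounts(), nReads = 0L,
        nExtensions = 0L)
}
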