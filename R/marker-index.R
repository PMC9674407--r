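## Marker array in suffix-rank order (MA), smearing (MA^w), and the sparse
## run-length S/E/X/B encoding.
##
## Bit vectors S (run starts) and E (run ends) are stored as the sorted
## 0-based positions of their 1 bits; rank1/select1 are answered from those
## positions. X is the flattened payload (one marker list per run, in order
## of appearance) and B marks each run's first element within X.

.rank1 <- function(pos, i) findInterval(i - 1, pos)   # ones at positions < i

## inverse suffix array: row holding the suffix that starts at each offset
.inverseSA <- function(fm) {
    isa <- integer(fm@n)
    isa[fm@sa + 1L] <- seq_len(fm@n) - 1L
    isa
}

#' Permute the dense marker array into suffix-rank order
#'
#' Computes MA, defined by `MA[i] = M[SA[i]]`: every marker at text offset
#' `p` is attached to the BWT row whose suffix starts at `p`.
#'
#' @param panel A [MarkerPanel-class].
#' @param fm The [FMIndex-class] over the panel text.
#' @return `data.frame` (`row`, `chrom`, `refOffset`, `allele`) sorted by
#'   `row`; rows without markers are absent.
#' @export
permuteMarkers <- function(panel, fm) {
    m <- panel@markers
    if (length(panel@text) != fm@n)
        stop("panel text and FM-index length mismatch")
    isa <- .inverseSA(fm)
    out <- data.frame(row = isa[m$textOffset + 1L], chrom = m$chrom,
                      refOffset = m$refOffset, allele = m$allele)
    out <- out[order(out$row, out$chrom, out$refOffset, out$allele), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

## Row-level entries of MA^w: marker at text offset p is attached to the
## rows of all suffixes starting in [p - w, p], clamped at the containing
## haplotype's start so a smear never crosses a separator.
.smearEntries <- function(panel, fm, w) {
    m <- panel@markers
    if (nrow(m) == 0L)
        return(data.frame(row = integer(0), chrom = integer(0),
                          refOffset = numeric(0), allele = integer(0)))
    hap <- .hapOf(panel, m$textOffset)
    starts <- pmax(m$textOffset - w, panel@hapStart[hap])
    lens <- m$textOffset - starts + 1L
    pos <- rep(starts, lens) + sequence(lens) - 1L
    idx <- rep(seq_len(nrow(m)), lens)
    isa <- .inverseSA(fm)
    data.frame(row = isa[pos + 1L], chrom = m$chrom[idx],
               refOffset = m$refOffset[idx], allele = m$allele[idx])
}

#' Sparse-encode per-row marker lists
#'
#' Detects maximal runs of consecutive rows carrying identical non-empty
#' marker lists (list identity is order-sensitive equality of encoded
#' marker words; lists are kept sorted by (chrom, refOffset, allele) so runs
#' are maximal) and stores them as the S/E/X/B structure.
#'
#' @param entries `data.frame` (`row`, `chrom`, `refOffset`, `allele`): the
#'   flattened per-row lists; a row absent from `entries` has the empty list.
#' @param n Number of BWT rows.
#' @param window The smearing window `w` the lists were built with (payload
#'   lists may not exceed `w + 1` markers).
#' @return A [SmearedMarkerArray-class].
#' @export
sparseEncode <- function(entries, n, window) {
    window <- as.integer(window)
    if (window < 0L) stop("window must be >= 0")
    if (nrow(entries) == 0L)
        return(methods::new("SmearedMarkerArray", window = window,
                            n = as.integer(n), startPos = integer(0),
                            endPos = integer(0), payload = .emptyCounts()[
                                c("chrom", "refOffset", "allele")],
                            listStart = integer(0), numRuns = 0L))
    entries <- unique(entries[order(entries$row, entries$chrom,
                                    entries$refOffset, entries$allele), ,
                              drop = FALSE])
    words <- .markerWords(entries)
    ur <- unique(entries$row)                     # sorted
    f <- factor(entries$row, levels = ur)
    sig <- vapply(split(words, f), paste, character(1), collapse = "|")
    len <- length(ur)
    newRun <- c(TRUE, diff(ur) != 1L | sig[-1L] != sig[-len])
    runEnd <- c(newRun[-1L], TRUE)
    startPos <- ur[newRun]
    endPos <- ur[runEnd]
    firstRows <- entries$row %in% startPos
    payload <- entries[firstRows, c("chrom", "refOffset", "allele"),
                       drop = FALSE]
    rownames(payload) <- NULL
    lens <- as.integer(table(factor(entries$row[firstRows],
                                    levels = startPos)))
    listStart <- c(0L, cumsum(lens))[seq_along(lens)]
    methods::new("SmearedMarkerArray", window = window, n = as.integer(n),
                 startPos = as.integer(startPos), endPos = as.integer(endPos),
                 payload = payload, listStart = as.integer(listStart),
                 numRuns = length(startPos))
}

#' Build the smeared marker array MA^w
#'
#' Attaches every marker to the rows of suffixes starting within `w`
#' positions left of it (clamped at the haplotype's start) and run-length
#' encodes the result, so that the decoded list at row `i` holds exactly
#' the markers of the dense array at text offsets `SA[i] .. SA[i] + w`.
#' `w = 0` reduces to the plain permuted marker array.
#'
#' @param panel A [MarkerPanel-class].
#' @param fm The [FMIndex-class] over the panel text.
#' @param window Smearing window `w >= 0`; default 19.
#' @return A [SmearedMarkerArray-class].
#' @export
buildMarkerIndex <- function(panel, fm, window = 19L) {
    if (window < 0L) stop("window must be >= 0")
    sparseEncode(.smearEntries(panel, fm, as.integer(window)), fm@n,
                 as.integer(window))
}

#' Access one row of a sparse marker array
#'
#' The sparse-access procedure over S/E/X/B: row `i` is non-empty iff
#' `S.rank1(i+1) > E.rank1(i)`; if so, with `e = E.rank1(i)`, the list is
#' `X[B.select1(e) .. B.select1(e+1))`.
#'
#' @param arr A [SmearedMarkerArray-class].
#' @param row 0-based row.
#' @return `data.frame` (`chrom`, `refOffset`, `allele`); zero rows when the
#'   list is empty.
#' @export
sparseAccess <- function(arr, row) {
    if (row < 0L || row >= arr@n) stop("row out of range")
    if (.rank1(arr@startPos, row + 1L) == .rank1(arr@endPos, row))
        return(arr@payload[0L, , drop = FALSE])
    e <- .rank1(arr@endPos, row)
    j <- arr@listStart[e + 1L]
    k <- if (e + 1L < arr@numRuns) arr@listStart[e + 2L] else nrow(arr@payload)
    out <- arr@payload[(j + 1L):k, , drop = FALSE]
    rownames(out) <- NULL
    out
}

## All distinct markers attached to any row in [lo, hi); used by the
## genotyping loop (per-extension evidence is deduplicated anyway).
.rangeMarkers <- function(arr, lo, hi) {
    if (arr@numRuns == 0L || hi <= lo) return(NULL)
    first <- .rank1(arr@endPos, lo) + 1L          # first run ending >= lo
    last <- findInterval(hi - 1L, arr@startPos)   # last run starting < hi
    if (first > last) return(NULL)
    j <- arr@listStart[first] + 1L
    k <- if (last < arr@numRuns) arr@listStart[last + 1L] else nrow(arr@payload)
    unique(arr@payload[j:k, , drop = FALSE])
}

#' Materialise a sparse marker array as a dense list
#'
#' One entry per row (a zero-row `data.frame` for empty rows). Intended for
#' small instances and oracle comparisons in tests.
#'
#' @param arr A [SmearedMarkerArray-class].
#' @return List of length `n` of `data.frame`s.
#' @export
decodeMarkerArray <- function(arr) {
    lapply(seq_len(arr@n) - 1L, function(i) sparseAccess(arr, i))
}

#' Encoded size of a sparse marker array
#'
#' A byte-accounting proxy for the structure's footprint: two length-`n`
#' bit vectors (S, E), one 64-bit word per payload marker (X), and one bit
#' per payload element (B).
#'
#' @param arr A [SmearedMarkerArray-class].
#' @return Numeric; size in bytes.
#' @export
markerIndexSize <- function(arr) {
    2 * ceiling(arr@n / 8) + 8 * nrow(arr@payload) +
        ceiling(nrow(arr@payload) / 8)
}
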