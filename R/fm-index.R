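## FM-index substrate: suffix array, BWT, C array, rank/select, backward
## search, LF and FL steps, and locate over a regularly sampled suffix array.
##
## All rows and text offsets are 0-based; suffix-array ranges are half-open
## [lo, hi), so a range is empty iff lo == hi and its width is the number of
## occurrences of the pattern matched so far.

## Desk-scale suffix array construction by prefix doubling; order() uses a
## radix sort on integer rank pairs, so each round is O(n).
.buildSuffixArray <- function(codes) {
    n <- length(codes)
    if (n == 1L) return(0L)
    rk <- codes
    k <- 1L
    repeat {
        r2 <- if (k < n) c(rk[(k + 1L):n], integer(k)) else integer(n)
        o <- order(rk, r2, method = "radix")
        b1 <- rk[o]; b2 <- r2[o]
        new <- cumsum(c(1L, as.integer(b1[-1L] != b1[-n] | b2[-1L] != b2[-n])))
        rk[o] <- new
        if (new[n] == n) break
        k <- k * 2L
    }
    sa <- integer(n)
    sa[rk] <- seq_len(n)
    sa - 1L
}

#' Build an FM-index over a symbol-coded text
#'
#' Constructs the suffix array (prefix doubling), BWT, C array, a full
#' occurrence-count rank structure, per-symbol select positions, the BWT
#' run count, and (optionally) a regularly sampled suffix array for locate
#' queries.
#'
#' @param text Either a character string over the panel alphabet
#'   (`$`, `#`, `A`, `C`, `G`, `N`, `T`) or an integer vector of internal
#'   symbol codes. Must end with the unique, lexicographically smallest
#'   sentinel `$`.
#' @param saSampleRate Integer `s`; if positive, suffix-array values that are
#'   multiples of `s` are retained so [locateRow()] can recover any `SA[row]`
#'   by LF-walking to a sampled row (text offset 0 is always a multiple, so
#'   every walk terminates within `s` steps). `0` disables the sample.
#' @return An [FMIndex-class].
#' @examples
#' fm <- buildFMIndex("ACGACG$")
#' suffixArray(fm)      # 6 3 0 4 1 5 2
#' @export
buildFMIndex <- function(text, saSampleRate = 0L) {
    codes <- if (is.character(text)) .encodeChars(text) else as.integer(text)
    if (anyNA(codes)) stop("text contains symbols outside the alphabet")
    n <- length(codes)
    if (n == 0L) stop("empty text")
    if (codes[n] != .SENTINEL || sum(codes == .SENTINEL) != 1L)
        stop("text must end with a unique sentinel '$'")
    sa <- .buildSuffixArray(codes)
    bwt <- codes[((sa - 1L) %% n) + 1L]
    tot <- tabulate(bwt, nbins = .NSYM)
    C <- c(0L, cumsum(tot))[seq_len(.NSYM)]
    occ <- vapply(seq_len(.NSYM), function(c) c(0L, cumsum(bwt == c)),
                  integer(n + 1L))
    selectPos <- lapply(seq_len(.NSYM), function(c) which(bwt == c))
    runCount <- if (n == 1L) 1L else sum(bwt[-1L] != bwt[-n]) + 1L
    saSampleRate <- as.integer(saSampleRate)
    sampVal <- rep(NA_integer_, n)
    if (saSampleRate > 0L) {
        hit <- sa %% saSampleRate == 0L
        sampVal[hit] <- sa[hit]
    }
    methods::new("FMIndex", n = n, sa = sa, bwt = bwt, cArr = C, occ = occ,
                 selectPos = selectPos, runCount = as.integer(runCount),
                 sampleRate = saSampleRate, sampVal = sampVal)
}

#' Extend a backward-search range by one character
#'
#' One step of backward search: given the half-open suffix-array range
#' `[lo, hi)` of suffixes prefixed by the pattern matched so far (`Q`),
#' returns the range of suffixes prefixed by `cQ` via two rank queries:
#' `lo' = C[c] + rank_c(lo)`, `hi' = C[c] + rank_c(hi)`.
#'
#' @param fm An [FMIndex-class].
#' @param lo,hi Half-open 0-based range (the full range is `[0, n)`).
#' @param c A single character, or an internal symbol code.
#' @return Integer vector `c(lo, hi)`; empty (`lo == hi`) if `cQ` does not
#'   occur, including when `c` is outside the alphabet.
#' @export
backwardExtend <- function(fm, lo, hi, c) {
    code <- if (is.character(c)) .CHAR2CODE[utf8ToInt(c)[1L]] else as.integer(c)
    if (is.na(code) || code < 1L || code > .NSYM) return(c(lo, lo))
    occ <- fm@occ
    base <- fm@cArr[code]
    c(base + occ[lo + 1L, code], base + occ[hi + 1L, code])
}

#' Count pattern occurrences by backward search
#'
#' @param fm An [FMIndex-class].
#' @param pattern Character string over the alphabet.
#' @return Integer vector `c(lo, hi)`: the maximal half-open suffix-array
#'   range whose suffixes are prefixed by `pattern` (width = occurrence
#'   count).
#' @export
patternRange <- function(fm, pattern) {
    codes <- .encodeChars(pattern)
    lo <- 0L; hi <- fm@n
    for (o in rev(seq_along(codes))) {
        r <- backwardExtend(fm, lo, hi, codes[o])
        lo <- r[1L]; hi <- r[2L]
        if (lo == hi) break
    }
    c(lo, hi)
}

#' Count occurrences of a pattern
#' @inheritParams patternRange
#' @return Integer: number of occurrences of `pattern` in the indexed text.
#' @export
countOccurrences <- function(fm, pattern) {
    r <- patternRange(fm, pattern)
    r[2L] - r[1L]
}

#' LF step: move one position left in the text
#'
#' `lfStep(row)` returns `C[L[row]] + rank_{L[row]}(row)`, the suffix-array
#' row holding the suffix that starts one text position to the left
#' (`SA[lfStep(row)] = (SA[row] - 1) mod n`). Vectorised over `row`.
#'
#' @param fm An [FMIndex-class].
#' @param row 0-based BWT row(s).
#' @return 0-based row(s).
#' @export
lfStep <- function(fm, row) {
    if (any(row < 0L | row >= fm@n)) stop("row out of range")
    cc <- fm@bwt[row + 1L]
    fm@cArr[cc] + fm@occ[cbind(row + 1L, cc)]
}

#' FL step: move one position right in the text
#'
#' The inverse of [lfStep()], implemented with a select query on the BWT of
#' the F-column symbol at the row: `SA[flStep(row)] = (SA[row] + 1) mod n`.
#' Vectorised over `row`.
#'
#' @inheritParams lfStep
#' @return 0-based row(s).
#' @export
flStep <- function(fm, row) {
    if (any(row < 0L | row >= fm@n)) stop("row out of range")
    cc <- findInterval(row, fm@cArr)          # F-column symbol at each row
    k <- row - fm@cArr[cc]                    # 0-based rank within symbol
    out <- integer(length(row))
    for (u in unique(cc))
        out[cc == u] <- fm@selectPos[[u]][k[cc == u] + 1L] - 1L
    out
}

#' Recover a suffix-array value from the sampled suffix array
#'
#' Walks [lfStep()] from `row` until a sampled row is reached, then adds the
#' number of steps taken: `locateRow(row) == SA[row]`. Requires the index to
#' have been built with `saSampleRate > 0`; text offset 0 is always sampled,
#' so the walk terminates within `s` steps.
#'
#' @inheritParams lfStep
#' @return 0-based text offset `SA[row]`.
#' @export
locateRow <- function(fm, row) {
    if (fm@sampleRate <= 0L) stop("index was built without a sampled suffix array")
    vapply(row, function(r) {
        t <- 0L
        while (is.na(fm@sampVal[r + 1L])) {
            r <- lfStep(fm, r)
            t <- t + 1L
        }
        fm@sampVal[r + 1L] + t
    }, integer(1))
}

#' Invert the BWT
#'
#' Reconstructs the text by LF-walking from the sentinel row; used as a
#' round-trip check that the index is self-consistent.
#'
#' @param fm An [FMIndex-class].
#' @return Character string: the original text.
#' @export
invertBWT <- function(fm) {
    n <- fm@n
    out <- integer(n)
    out[n] <- .SENTINEL
    r <- 0L   # row 0 is the sentinel suffix
    for (i in rev(seq_len(n - 1L))) {
        out[i] <- fm@bwt[r + 1L]
        r <- lfStep(fm, r)
    }
    .decodeCodes(out)
}
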