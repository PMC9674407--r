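## Internal alphabet of the concatenated panel text.
##
## Symbols are held as small integer codes so that lexicographic order is
## fixed by construction (and therefore suffix-array values are reproducible):
##
##   1 = "$"  sentinel   (unique, lexicographically smallest, terminates T)
##   2 = "#"  separator  (ends every haplotype; smaller than all DNA symbols)
##   3 = "A", 4 = "C", 5 = "G", 6 = "N", 7 = "T"
##
## "N" sorts between G and T because the order is alphabetical over the DNA
## symbols; any fixed order works, this one is documented and frozen.

.ALPHABET <- c("$", "#", "A", "C", "G", "N", "T")
.SENTINEL <- 1L
.SEPARATOR <- 2L
.NSYM <- 7L
.DNA_CODES <- c(3L, 4L, 5L, 7L)  # A, C, G, T: the only codes a read may use

.CHAR2CODE <- local({
    m <- rep(NA_integer_, 256L)
    m[utf8ToInt("$")] <- 1L
    m[utf8ToInt("#")] <- 2L
    m[utf8ToInt("A")] <- 3L
    m[utf8ToInt("C")] <- 4L
    m[utf8ToInt("G")] <- 5L
    m[utf8ToInt("N")] <- 6L
    m[utf8ToInt("T")] <- 7L
    m[utf8ToInt("a")] <- 3L
    m[utf8ToInt("c")] <- 4L
    m[utf8ToInt("g")] <- 5L
    m[utf8ToInt("n")] <- 6L
    m[utf8ToInt("t")] <- 7L
    m
})

## DNA complement on codes; N -> N, non-DNA -> NA
.COMP <- local({
    m <- rep(NA_integer_, .NSYM)
    m[3L] <- 7L; m[7L] <- 3L; m[4L] <- 5L; m[5L] <- 4L; m[6L] <- 6L
    m
})

#' Encode a character string into internal symbol codes
#'
#' Maps `$`, `#`, `A`, `C`, `G`, `N`, `T` (case-insensitive for DNA) to the
#' package's fixed integer alphabet. Unknown characters become `NA`.
#'
#' @param x A single character string.
#' @return Integer vector of codes, one per character.
#' @keywords internal
.encodeChars <- function(x) {
    if (!nzchar(x)) return(integer(0))
    .CHAR2CODE[utf8ToInt(x)]
}

.decodeCodes <- function(codes) {
    paste(.ALPHABET[codes], collapse = "")
}

## Reverse complement at code level (codes must be DNA or N).
.revcompCodes <- function(codes) {
    rev(.COMP[codes])
}
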