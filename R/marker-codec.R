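## 64-bit marker word codec.
##
## A marker (chrom, refOffset, allele) is packed into a 64-bit word with a
## 12-bit chromosome field (high bits), a 48-bit within-chromosome offset,
## and a 4-bit allele field (0 = reference allele, k = k-th alternate).
## R has no native 64-bit integer, so the word is realised as a 16-hex-digit
## string: 3 hex digits of chromosome, 12 of offset, 1 of allele. The
## mapping is bijective and decode is total on 16-hex-digit strings.

.MAX_CHROM <- 4096          # 2^12
.MAX_OFFSET <- 2^48
.MAX_ALLELE <- 16L          # 2^4

.hex48 <- function(x) {
    hi <- floor(x / 16777216)           # 2^24
    lo <- x - hi * 16777216
    sprintf("%06x%06x", as.integer(hi), as.integer(lo))
}

#' Encode a marker as a 64-bit word
#'
#' Packs a marker triple into the 12/48/4-bit word layout (chromosome index
#' in the high bits, within-chromosome offset in the middle, allele number
#' in the low 4 bits), represented as a 16-hex-digit string.
#'
#' @param chrom Integer vector; 0-based chromosome index (< 4096). The first
#'   chromosome of the reference encodes as `0x000`, the second as `0x001`.
#' @param refOffset Numeric vector; 0-based offset within the chromosome
#'   (< 2^48).
#' @param allele Integer vector; 0 for the reference allele, k >= 1 for the
#'   k-th alternate (< 16).
#' @return Character vector of 16-hex-digit words.
#' @seealso [decodeMarker()]
#' @examples
#' encodeMarker(0, 0, 0)        # "0000000000000000"
#' decodeMarker(encodeMarker(1, 500, 1))
#' @export
encodeMarker <- function(chrom, refOffset, allele) {
    chrom <- as.integer(chrom)
    allele <- as.integer(allele)
    refOffset <- as.numeric(refOffset)
    if (any(is.na(chrom)) || any(chrom < 0L) || any(chrom >= .MAX_CHROM))
        stop("chromosome index out of range [0, 4096)")
    if (any(is.na(refOffset)) || any(refOffset < 0) || any(refOffset >= .MAX_OFFSET))
        stop("reference offset out of range [0, 2^48)")
    if (any(is.na(allele)) || any(allele < 0L) || any(allele >= .MAX_ALLELE))
        stop("allele out of range [0, 16)")
    paste0(sprintf("%03x", chrom), .hex48(refOffset), sprintf("%01x", allele))
}

#' Decode a 64-bit marker word
#'
#' Inverse of [encodeMarker()]; total on 16-hex-digit strings (every word
#' decodes to some in-range triple by construction of the field masks).
#'
#' @param word Character vector of 16-hex-digit words.
#' @return `data.frame` with columns `chrom`, `refOffset`, `allele`.
#' @export
decodeMarker <- function(word) {
    if (any(nchar(word) != 16L) || any(grepl("[^0-9a-fA-F]", word)))
        stop("marker word must be a 16-hex-digit string")
    data.frame(
        chrom = strtoi(substr(word, 1L, 3L), 16L),
        refOffset = strtoi(substr(word, 4L, 9L), 16L) * 16777216 +
            strtoi(substr(word, 10L, 15L), 16L),
        allele = strtoi(substr(word, 16L, 16L), 16L)
    )
}

## Order-sensitive list identity for run merging uses these words.
.markerWords <- function(df) encodeMarker(df$chrom, df$refOffset, df$allele)
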