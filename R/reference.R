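#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA reference, normalises sequences to upper case,
#' strips FASTA descriptions from names, and maps IUPAC ambiguity codes
#' other than A/C/G/T to `N`. Chromosome order is the order of appearance
#' in the file and defines the 0-based chromosome index used in marker
#' words.
#'
#' @param fastaPath Path to a FASTA file.
#' @return A named character vector of chromosome sequences over
#'   \{A,C,G,T,N\}, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "acgta"), fa)
#' loadReference(fa)
#' @export
loadReference <- function(fastaPath) {
    if (!file.exists(fastaPath))
        stop("FASTA file not found: ", fastaPath)
    ss <- Biostrings::readBStringSet(fastaPath)
    seqs <- toupper(as.character(ss))
    nm <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(nm))
        stop("duplicate chromosome name in FASTA: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    if (any(!nzchar(seqs)))
        stop("empty sequence in FASTA: ", paste(nm[!nzchar(seqs)], collapse = ", "))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
        ## ambiguity codes collapse to N; anything non-IUPAC is an error
        if (any(grepl("[^ACGTNRYSWKMBDHVU]", seqs)))
            stop("non-IUPAC character in FASTA sequence")
        seqs <- gsub("[RYSWKMBDHVU]", "N", seqs)
    }
    names(seqs) <- nm
    seqs
}
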