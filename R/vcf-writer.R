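## Genotyped-VCF output. The file is written as plain text (the layout is
## simple and fixed); emitted files are round-trip validated through
## VariantAnnotation::readVcf in the test suite.

#' Write genotype calls to a VCF file
#'
#' Emits a single-sample VCF 4.2 with `GT`, `DP` (total observations `k`),
#' `AD` (reference and per-ALT observation counts) and, for diploid calls,
#' `GL` (log10 genotype likelihoods for 0/0, 0/ALT, ALT/ALT). REF/ALT
#' strings are the panel's site alleles; positions are 1-based anchors.
#'
#' @param calls `data.frame` from [callGenotypes()], sorted by
#'   (chrom, refOffset).
#' @param index A [PanelIndex-class] or [MarkerPanel-class] (for contig
#'   names and lengths).
#' @param path Output file path.
#' @param sampleName Sample column name; default `"DONOR"`.
#' @return Invisibly, `path`.
#' @export
writeCallsVcf <- function(calls, index, path, sampleName = "DONOR") {
    panel <- if (methods::is(index, "PanelIndex")) index@panel else index
    diploid <- "g" %in% names(calls)
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=markerArray",
        paste0("##contig=<ID=", panel@refNames, ",length=", panel@refLens,
               ">"),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total allele observations at the site\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Observations per allele (REF first)\">",
        if (diploid)
            "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"log10 genotype likelihoods (0/0, 0/ALT, ALT/ALT)\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleName), collapse = "\t")
    )
    body <- character(0)
    if (nrow(calls)) {
        if (is.unsorted(order(calls$chrom, calls$refOffset)))
            stop("calls must be sorted by (chrom, refOffset)")
        fmt <- if (diploid) "GT:DP:AD:GL" else "GT:DP:AD"
        sample <- if (diploid) {
            paste(calls$gt, calls$k, calls$ad,
                  paste(sprintf("%.4f", calls$GL2),   # GL for 0/0 first
                        sprintf("%.4f", calls$GL1),
                        sprintf("%.4f", calls$GL0), sep = ","),
                  sep = ":")
        } else {
            paste(calls$gt, calls$k, calls$ad, sep = ":")
        }
        body <- paste(calls$chromName,
                      format(calls$refOffset + 1, scientific = FALSE,
                             trim = TRUE),
                      ".", calls$ref, calls$alts, ".", ".", ".",
                      fmt, sample, sep = "\t")
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a genotyped VCF back into a calls table
#'
#' Round-trip companion of [writeCallsVcf()], parsing through
#' `VariantAnnotation::readVcf`.
#'
#' @param path VCF file path.
#' @param index A [PanelIndex-class] or [MarkerPanel-class] (for the
#'   chromosome index).
#' @return `data.frame` with `chrom`, `chromName`, `refOffset`, `ref`,
#'   `alts`, `gt`, `k` (DP), `ad`.
#' @export
readCallsVcf <- function(path, index) {
    panel <- if (methods::is(index, "PanelIndex")) index@panel else index
    vcf <- VariantAnnotation::readVcf(path, genome = "panel")
    rr <- SummarizedExperiment::rowRanges(vcf)
    chromName <- as.character(GenomeInfoDb::seqnames(rr))
    altL <- as(VariantAnnotation::alt(vcf), "CharacterList")
    g <- VariantAnnotation::geno(vcf)
    dp <- if (!is.null(g$DP)) as.integer(g$DP[, 1L]) else NA_integer_
    ad <- if (!is.null(g$AD)) {
        vapply(seq_len(nrow(g$AD)), function(i)
            paste(unlist(g$AD[i, 1L]), collapse = ","), character(1))
    } else NA_character_
    out <- data.frame(
        chrom = match(chromName, panel@refNames) - 1L,
        chromName = chromName,
        refOffset = BiocGenerics::start(rr) - 1,
        ref = as.character(VariantAnnotation::ref(vcf)),
        alts = vapply(as.list(altL), paste, character(1), collapse = ","),
        gt = if (!is.null(g$GT)) g$GT[, 1L] else NA_character_,
        k = dp, ad = ad)
    rownames(out) <- NULL
    out
}
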