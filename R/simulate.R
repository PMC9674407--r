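## Deterministic synthetic fixtures: toy references, phased haplotype panels
## (VCF), truth tables, and error-bearing diploid read sets.
##
## The generator emulates a small resequencing panel: a random reference,
## biallelic SNVs and short indels placed with at least a 1 bp gap between
## REF spans (so sites never overlap or abut), and per-site alternate-allele
## frequencies drawn from a low-frequency-skewed Beta(0.8, 4) spectrum so
## that minimum-allele-frequency filtering has something to filter. Variant
## carriers are assigned independently per haplotype; samples are diploid
## (two consecutive haplotypes).

.randSeq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a reference, a phased haplotype panel and its truth table
#'
#' Writes a FASTA reference, a sorted, phased multi-sample VCF and a
#' tab-separated truth table (site by haplotype allele matrix) to `dir`;
#' all output is byte-identical for a fixed `seed`.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param nChroms Number of chromosomes (default 1).
#' @param chromLength Length of each chromosome in bp (default 50000).
#' @param nHaplotypes Number of panel haplotypes; must be even, two per
#'   diploid sample (default 12 — six samples, so holding one sample out as
#'   a donor leaves a 10-haplotype panel).
#' @param snvRate Per-base probability of a SNV site (default 0.01).
#' @param indelRate Per-base probability of an indel site (default 0.001).
#' @param maxIndelLen Maximum inserted/deleted length (default 10).
#' @param afShape1,afShape2 Beta parameters of the alternate-allele
#'   frequency spectrum (default 0.8 and 4).
#' @return List with `fasta`, `vcf`, `truth` (file paths), `ref` (named
#'   character vector), `sites` (`data.frame`: `chrom`, `chromName`, `pos`
#'   1-based anchor, `type`, `ref`, `alt`), `hapAlleles` (sites x
#'   haplotypes 0/1 matrix), `samples`, and the generator parameters.
#' @export
simulatePanel <- function(seed, dir, nChroms = 1L, chromLength = 50000L,
                          nHaplotypes = 12L, snvRate = 0.01,
                          indelRate = 0.001, maxIndelLen = 10L,
                          afShape1 = 0.8, afShape2 = 4) {
    if (nHaplotypes %% 2L != 0L)
        stop("nHaplotypes must be even (two per diploid sample)")
    if (snvRate < 0 || snvRate > 1 || indelRate < 0 || indelRate > 1)
        stop("rates must be in [0, 1]")
    if (snvRate + indelRate > 0.2)
        stop("variant rates too high to place non-overlapping sites; ",
             "reduce snvRate/indelRate below a combined 0.2")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    chromNames <- paste0("chr", seq_len(nChroms))
    ref <- stats::setNames(
        vapply(seq_len(nChroms), function(i) .randSeq(chromLength),
               character(1)), chromNames)

    siteRows <- list()
    for (ci in seq_len(nChroms)) {
        refSeq <- ref[[ci]]
        L <- nchar(refSeq)
        snvPos <- which(stats::runif(L) < snvRate)
        indelPos <- which(stats::runif(L) < indelRate)
        indelPos <- indelPos[indelPos <= L - maxIndelLen - 1L]
        cand <- rbind(
            if (length(snvPos))
                data.frame(pos = snvPos, type = "snv"),
            if (length(indelPos))
                data.frame(pos = indelPos,
                           type = sample(c("ins", "del"), length(indelPos),
                                         replace = TRUE))
        )
        if (is.null(cand) || nrow(cand) == 0L) next
        cand <- cand[order(cand$pos), , drop = FALSE]
        cand <- cand[!duplicated(cand$pos), , drop = FALSE]
        prevEnd <- -1L
        for (i in seq_len(nrow(cand))) {
            p <- cand$pos[i]
            type <- cand$type[i]
            len <- if (type == "snv") 0L else sample.int(maxIndelLen, 1L)
            spanEnd <- if (type == "del") p + len else p
            if (p <= prevEnd + 1L) next               # keep a >= 1 bp gap
            base <- substr(refSeq, p, p)
            if (type == "snv") {
                alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
                refStr <- base
            } else if (type == "ins") {
                alt <- paste0(base, .randSeq(len))
                refStr <- base
            } else {
                refStr <- substr(refSeq, p, p + len)
                alt <- base
            }
            siteRows[[length(siteRows) + 1L]] <- data.frame(
                chrom = ci - 1L, chromName = chromNames[ci], pos = p,
                type = type, ref = refStr, alt = alt)
            prevEnd <- spanEnd
        }
    }
    sites <- if (length(siteRows)) do.call(rbind, siteRows) else
        data.frame(chrom = integer(0), chromName = character(0),
                   pos = integer(0), type = character(0),
                   ref = character(0), alt = character(0))
    rownames(sites) <- NULL

    hapAlleles <- matrix(0L, nrow(sites), nHaplotypes)
    if (nrow(sites)) {
        for (i in seq_len(nrow(sites))) {
            p <- stats::rbeta(1L, afShape1, afShape2)
            carriers <- stats::rbinom(nHaplotypes, 1L, p)
            if (sum(carriers) == 0L)
                carriers[sample.int(nHaplotypes, 1L)] <- 1L
            hapAlleles[i, ] <- carriers
        }
    }
    nSamples <- nHaplotypes %/% 2L
    samples <- paste0("S", seq_len(nSamples))

    fasta <- file.path(dir, "ref.fa")
    faLines <- unlist(lapply(chromNames, function(nm) {
        s <- ref[[nm]]
        c(paste0(">", nm),
          substring(s, seq(1L, nchar(s), 60L),
                    pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
    }))
    writeLines(faLines, fasta)

    vcf <- file.path(dir, "panel.vcf")
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chromNames, ",length=", chromLength,
                    ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    body <- character(0)
    if (nrow(sites)) {
        gtCols <- vapply(seq_len(nSamples), function(j) {
            paste(hapAlleles[, 2L * j - 1L], hapAlleles[, 2L * j],
                  sep = "|")
        }, character(nrow(sites)))
        gtCols <- matrix(gtCols, nrow = nrow(sites))
        body <- paste(sites$chromName, sites$pos, ".", sites$ref,
                      sites$alt, ".", "PASS", ".", "GT",
                      apply(gtCols, 1L, paste, collapse = "\t"),
                      sep = "\t")
    }
    writeLines(c(hdr, body), vcf)

    truth <- file.path(dir, "truth.tsv")
    hapNames <- as.vector(t(outer(samples, 1:2, paste, sep = "_")))
    tdf <- cbind(sites, stats::setNames(as.data.frame(hapAlleles), hapNames))
    utils::write.table(tdf, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(fasta = fasta, vcf = vcf, truth = truth, ref = ref, sites = sites,
         hapAlleles = hapAlleles, samples = samples, hapNames = hapNames,
         seed = seed, nChroms = nChroms, chromLength = chromLength,
         nHaplotypes = nHaplotypes, snvRate = snvRate,
         indelRate = indelRate, maxIndelLen = maxIndelLen)
}

## donor haplotype sequence for one chromosome
.donorChromSeq <- function(sim, ci, hapIdx) {
    ix <- which(sim$sites$chrom == ci - 1L)
    siteList <- lapply(ix, function(i) list(
        refOffset = sim$sites$pos[i] - 1,
        refLen = nchar(sim$sites$ref[i]),
        ref = sim$sites$ref[i],
        alts = sim$sites$alt[i]))
    alleles <- if (length(ix)) sim$hapAlleles[ix, hapIdx] else integer(0)
    .spliceChrom(sim$ref[[ci]], siteList, alleles)$seq
}

#' Simulate diploid sequencing reads from a donor sample
#'
#' Samples error-bearing reads uniformly from both haplotypes of one panel
#' sample, on both strands, and writes a FASTQ plus the donor's diploid
#' truth genotypes at every panel site. Read names record the source
#' haplotype, chromosome, 0-based start on the haplotype, and strand.
#'
#' @param sim Result of [simulatePanel()].
#' @param donorSample Sample name whose two haplotypes are sequenced
#'   (default: the last sample).
#' @param readLength Read length in bp (default 150).
#' @param coverage Mean fold coverage over the (haploid) reference length
#'   (default 25).
#' @param errorRate Per-base substitution error probability (default 0;
#'   indel sequencing errors are not modelled).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with `fastq` and `truth` (file paths), `reads` (character
#'   vector), and `truthGenotypes` (`data.frame`: `chrom`, `refOffset`
#'   0-based anchor, `type`, `a1`, `a2`, `g` reference copies).
#' @export
simulateReads <- function(sim, donorSample = NULL, readLength = 150L,
                          coverage = 25, errorRate = 0, seed = 1L,
                          dir = dirname(sim$fasta)) {
    if (coverage <= 0) stop("coverage must be > 0")
    if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
    if (is.null(donorSample))
        donorSample <- sim$samples[length(sim$samples)]
    j <- match(donorSample, sim$samples)
    if (is.na(j)) stop("unknown donor sample: ", donorSample)
    if (readLength > min(nchar(sim$ref)))
        stop("readLength exceeds chromosome length")
    set.seed(seed)
    hapIdx <- c(2L * j - 1L, 2L * j)
    donor <- lapply(1:2, function(h)
        vapply(seq_len(sim$nChroms), function(ci)
            .donorChromSeq(sim, ci, hapIdx[h]), character(1)))

    genomeSize <- sum(nchar(sim$ref))
    nReads <- as.integer(round(coverage * genomeSize / readLength))
    hap <- sample.int(2L, nReads, replace = TRUE)
    lens1 <- nchar(donor[[1L]]); lens2 <- nchar(donor[[2L]])
    names <- character(nReads); seqs <- character(nReads)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nReads)) {
        lens <- if (hap[i] == 1L) lens1 else lens2
        ci <- sample.int(sim$nChroms, 1L, prob = lens)
        start <- sample.int(lens[ci] - readLength + 1L, 1L) - 1L
        s <- substr(donor[[hap[i]]][ci], start + 1L, start + readLength)
        nErr <- stats::rbinom(1L, readLength, errorRate)
        if (nErr > 0L) {
            at <- sample.int(readLength, nErr)
            ch <- strsplit(s, "", fixed = TRUE)[[1L]]
            for (p in at)
                ch[p] <- sample(setdiff(bases, ch[p]), 1L)
            s <- paste(ch, collapse = "")
        }
        strand <- if (stats::runif(1L) < 0.5) "+" else "-"
        if (strand == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        names[i] <- sprintf("r%d hap=%d chrom=%s start=%d strand=%s",
                            i, hap[i], names(sim$ref)[ci], start, strand)
        seqs[i] <- s
    }
    fastq <- file.path(dir, sprintf("reads_%s_e%g.fq", donorSample,
                                    errorRate))
    qual <- strrep("I", readLength)
    writeLines(as.vector(rbind(paste0("@", names), seqs, "+", qual)), fastq)

    a1 <- if (nrow(sim$sites)) sim$hapAlleles[, hapIdx[1L]] else integer(0)
    a2 <- if (nrow(sim$sites)) sim$hapAlleles[, hapIdx[2L]] else integer(0)
    truthGenotypes <- data.frame(
        chrom = sim$sites$chrom, refOffset = sim$sites$pos - 1,
        type = sim$sites$type, a1 = a1, a2 = a2,
        g = (a1 == 0L) + (a2 == 0L))
    truthPath <- file.path(dir, sprintf("donor_truth_%s.tsv", donorSample))
    utils::write.table(truthGenotypes, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fastq = fastq, truth = truthPath, reads = seqs,
         readNames = names, truthGenotypes = truthGenotypes)
}
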