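## a deterministic two-sample panel with one SNV in an otherwise
## invariant region, for targeted genotyping-loop checks
snvPanelIndex <- function(seed = 5, len = 300L, sitePos = 150L,
                          gts = "0|1", window = 19L) {
    set.seed(seed)
    refSeq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
    base <- substr(refSeq, sitePos, sitePos)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = refSeq))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           sprintf("##contig=<ID=chrA,length=%d>", len),
                           paste(c("chrA", sitePos, ".", base, alt, ".",
                                   "PASS", ".", "GT", gts),
                                 collapse = "\t"),
                           samples = paste0("S", seq_along(gts)))
    buildPanelIndex(fa, vcf, window = window, saSampleRate = 4L)
}

test_that("an exact read over one SNV yields one extension with that allele", {
    idx <- snvPanelIndex()
    panel <- idx@panel
    ## read = 100 bp of the alt-carrying haplotype (H2), centred on the site
    txt <- panelTextString(panel)
    altHap <- which(panel@hapNames == "S1_2")
    m <- markerTable(panel)
    mAlt <- m[m$allele == 1L, ]
    readStart <- mAlt$textOffset - 50L            # 0-based in text
    read <- substr(txt, readStart + 1L, readStart + 100L)
    set.seed(1)
    ev <- genotypeRead(read, idx, minSeedLen = 80L)
    expect_length(ev, 1L)
    expect_identical(ev[[1]]$matchLen, 100L)
    expect_identical(ev[[1]]$sites$refOffset, mAlt$refOffset)
    expect_identical(ev[[1]]$sites$allele, 1L)
    ## the FL oracle on the matched substring confirms the tallied site
    fl <- flMarkerQuery(read, idx)
    expect_true(any(fl$refOffset == mAlt$refOffset & fl$allele == 1L))

    ## the reference-carrying haplotype gives the 0 allele
    refStart <- m$textOffset[m$allele == 0L][2] - 50L   # H1's marker
    read0 <- substr(txt, refStart + 1L, refStart + 100L)
    set.seed(2)
    ev0 <- genotypeRead(read0, idx, minSeedLen = 80L)
    expect_length(ev0, 1L)
    expect_identical(ev0[[1]]$sites$allele, 0L)
})

test_that("garbage reads and short matches produce no evidence", {
    idx <- snvPanelIndex()
    set.seed(3)
    junk <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
    ## a random 100-mer is absent from a 300 bp panel; every extension stays
    ## far below the 80 bp seed threshold
    expect_length(genotypeRead(junk, idx, minSeedLen = 80L), 0L)
    expect_length(genotypeRead("", idx), 0L)
    ## N terminates the extension: splitting a perfect read in the middle
    ## with N leaves two halves below the threshold
    txt <- panelTextString(idx@panel)
    read <- substr(txt, 31L, 130L)
    substr(read, 50L, 50L) <- "N"
    set.seed(4)
    expect_length(genotypeRead(read, idx, minSeedLen = 80L), 0L)
})

test_that("conflicting alleles at a poked site discard the extension", {
    ## two haplotype groups differ at one site; the read matches an
    ## invariant region ending one base left of the site, so the first
    ## window query sees both alleles at once
    idx <- snvPanelIndex(seed = 6, len = 300L, sitePos = 201L,
                         gts = c("0|0", "1|1"))
    panel <- idx@panel
    refSeq <- substr(panelTextString(panel), 1, 300)
    read <- substr(refSeq, 101L, 200L)       # ends at 0-based offset 199
    set.seed(5)
    ev <- genotypeRead(read, idx, minSeedLen = 80L)
    expect_length(ev, 0L)
})

test_that("FL, locate and naive marker queries agree exactly", {
    set.seed(47)
    for (seed in c(51, 53, 59)) {
        tp <- tinyPanelIndex(seed, chromLength = 300L, nHaplotypes = 4L,
                             snvRate = 0.03, indelRate = 0.008)
        idx <- tp$idx
        txt <- panelTextString(idx@panel)
        for (j in 1:12) {
            pat <- if (j %% 3 == 0) {
                paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                      collapse = "")
            } else {
                ## window drawn near a marker so overlaps actually occur
                m <- markerTable(idx@panel)
                p <- m$textOffset[sample.int(nrow(m), 1)]
                s <- max(1L, p - sample(0:12, 1))
                substr(txt, s, min(nchar(txt) - 2L, s + sample(6:20, 1)))
            }
            if (grepl("[#$]", pat) || !nzchar(pat)) next
            fl <- flMarkerQuery(pat, idx)
            lq <- locateMarkerQuery(pat, idx)
            nv <- naiveMarkerOverlap(idx, pat)
            expect_identical(fl, lq)
            expect_identical(fl, nv)
        }
    }
    ## absent pattern: empty result from both strategies
    tp <- tinyPanelIndex(61, chromLength = 200L)
    expect_identical(nrow(flMarkerQuery("ACGTACGTACGTACGTACGTACGTAC",
                                        tp$idx)), 0L)
    expect_identical(nrow(locateMarkerQuery("ACGTACGTACGTACGTACGTACGTAC",
                                            tp$idx)), 0L)
    expect_error(flMarkerQuery("", tp$idx), "non-empty")
})

test_that("evidence accumulation counts l and k correctly", {
    site <- data.frame(chrom = 0L, refOffset = 100, allele = 0L)
    ev <- replicate(10, list(sites = site, matchLen = 90L, strand = "+"),
                    simplify = FALSE)
    tab <- accumulateEvidence(ev)
    cnt <- evidenceCounts(tab)
    expect_identical(sum(cnt$count[cnt$allele == 0L]), 10L)  # l = 10
    expect_identical(sum(cnt$count), 10L)                    # k = 10
    ## mixed 5 ref + 5 alt at one site
    alt <- data.frame(chrom = 0L, refOffset = 100, allele = 1L)
    ev2 <- c(replicate(5, list(sites = site, matchLen = 90L, strand = "+"),
                       simplify = FALSE),
             replicate(5, list(sites = alt, matchLen = 90L, strand = "-"),
                       simplify = FALSE))
    cnt2 <- evidenceCounts(accumulateEvidence(ev2))
    expect_identical(cnt2$count[cnt2$allele == 0L], 5L)
    expect_identical(sum(cnt2$count), 10L)
    ## empty evidence leaves the table unchanged
    tab3 <- accumulateEvidence(list(), tab)
    expect_identical(evidenceCounts(tab3), evidenceCounts(tab))
})

test_that("genotyping is bit-identical under a fixed strand seed", {
    tp <- tinyPanelIndex(67, chromLength = 800L, nHaplotypes = 4L)
    sim <- tp$sim
    rd <- simulateReads(sim, "S1", readLength = 100L, coverage = 8,
                        errorRate = 0.005, seed = 68, dir = tempdir())
    t1 <- genotypeReads(rd$reads, tp$idx, minSeedLen = 80L, seed = 99)
    t2 <- genotypeReads(rd$reads, tp$idx, minSeedLen = 80L, seed = 99)
    expect_identical(evidenceCounts(t1), evidenceCounts(t2))
    expect_identical(t1@nExtensions, t2@nExtensions)
})

test_that("tallied sites are contained in the exact-overlap oracle", {
    ## error-free reads from indexed haplotypes: every tallied (site,
    ## allele) must be overlapped by the read's occurrence, or lie exactly
    ## one position past it (the first window query of an extension spans
    ## SA[i]..SA[i]+w while only w characters have matched)
    tp <- tinyPanelIndex(71, chromLength = 1000L, nHaplotypes = 4L,
                         snvRate = 0.02, indelRate = 0.004)
    idx <- tp$idx
    txt <- panelTextString(idx@panel)
    panel <- idx@panel
    m <- markerTable(panel)
    set.seed(72)
    for (i in 1:25) {
        h <- sample.int(panel@hapCount, 1)
        s <- panel@hapStart[h] +
            sample.int(panel@hapLen[h] - 100L, 1) - 1L
        read <- substr(txt, s + 1L, s + 100L)
        ev <- genotypeRead(read, idx, minSeedLen = 80L)
        if (length(ev) == 0L) next
        occ <- naiveOccurrences(txt, read)
        allowed <- unique(do.call(rbind, lapply(occ, function(p) {
            sel <- m$textOffset >= p & m$textOffset <= p + nchar(read)
            m[sel, c("chrom", "refOffset", "allele")]
        })))
        for (e in ev) {
            got <- paste(e$sites$chrom, e$sites$refOffset, e$sites$allele)
            ok <- paste(allowed$chrom, allowed$refOffset, allowed$allele)
            expect_true(all(got %in% ok))
        }
    }
})
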