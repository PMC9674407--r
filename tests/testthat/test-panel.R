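## splice expected haplotypes by hand, independently of .spliceChrom
handSplice <- function(refSeq, pos0, refLen, alleleStr) {
    out <- ""
    cur <- 0L
    for (i in seq_along(pos0)) {
        out <- paste0(out, substr(refSeq, cur + 1L, pos0[i]), alleleStr[i])
        cur <- pos0[i] + refLen[i]
    }
    paste0(out, substr(refSeq, cur + 1L, nchar(refSeq)))
}

test_that("a single SNV produces per-haplotype markers and one edit", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "ACGTA"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=5>",
                           "chrA\t4\t.\tT\tG\t.\tPASS\t.\tGT\t0|1")
    panel <- buildPanel(loadReference(fa), vcf)
    txt <- panelTextString(panel)
    expect_identical(txt, "ACGTA#ACGTA#ACGGA#$")
    ## markers at the polymorphic column in T_0, H1 (ref) and H2 (alt)
    m <- markerTable(panel)
    expect_identical(nrow(m), 3L)
    expect_identical(m$refOffset, rep(3, 3))
    expect_identical(m$chrom, rep(0L, 3))
    ## text offsets: column 3 of each haplotype (haplotypes start at 0, 6, 12)
    expect_identical(m$textOffset, c(3L, 9L, 15L))
    expect_identical(m$allele, c(0L, 0L, 1L))
    e <- editTable(panel)
    expect_identical(e$id, 1L)
    expect_identical(e$type, "sub")
    expect_identical(e$value, "G")
})

test_that("the frequency filter removes marks but keeps spliced alleles", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "ACGTA"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=5>",
                           "chrA\t4\t.\tT\tG\t.\tPASS\t.\tGT\t0|1")
    ## alt frequency is 1/3 over {T_0, H1, H2}; 1/3 <= 0.6 so no marks
    panel <- buildPanel(loadReference(fa), vcf, minAf = 0.6)
    expect_identical(nrow(markerTable(panel)), 0L)
    expect_identical(panelTextString(panel), "ACGTA#ACGTA#ACGGA#$")
    expect_false(any(siteTable(panel)$marked))
})

test_that("indel marks sit on the single base left of the indel", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "AACCT"))
    ## 2 bp deletion of "CC": VCF anchors at POS 2 (REF "ACC", ALT "A")
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=5>",
                           "chrA\t2\t.\tACC\tA\t.\tPASS\t.\tGT\t1|1")
    panel <- buildPanel(loadReference(fa), vcf)
    m <- markerTable(panel)
    ## one marked position per haplotype (offset of the base at POS 2),
    ## regardless of the deletion's length
    expect_identical(unique(m$refOffset), 1)
    expect_identical(nrow(m), 3L)
    ## the deleted haplotypes are 2 bp shorter
    expect_identical(panelTextString(panel), "AACCT#AAT#AAT#$")
    ## left-of-indel rule: marked position precedes the first deleted base
    expect_true(all(m$refOffset < 2))
    e <- editTable(panel)
    expect_identical(e$type, "del")
    expect_identical(e$value, "2")
    ## suffixes starting at the marked position include the allele: the
    ## carrier haplotype reads "AT..." from its marker, the reference "AC..."
    txt <- panelTextString(panel)
    expect_identical(substr(txt, m$textOffset[2] + 1, m$textOffset[2] + 2),
                     "AT")
    expect_identical(substr(txt, m$textOffset[1] + 1, m$textOffset[1] + 2),
                     "AC")
})

test_that("insertions are anchored left and spliced into carriers", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "AACCT"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=5>",
                           "chrA\t2\t.\tA\tAGG\t.\tPASS\t.\tGT\t0|1")
    panel <- buildPanel(loadReference(fa), vcf)
    expect_identical(panelTextString(panel), "AACCT#AACCT#AAGGCCT#$")
    m <- markerTable(panel)
    expect_identical(unique(m$refOffset), 1)
    e <- editTable(panel)
    expect_identical(e$type, "ins")
    expect_identical(e$value, "GG")
})

test_that("abutting substitution records collapse into a single site", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "AACGTT"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=6>",
                           c("chrA\t3\t.\tC\tG\t.\tPASS\t.\tGT\t1|0",
                             "chrA\t4\t.\tG\tT\t.\tPASS\t.\tGT\t1|1"))
    panel <- buildPanel(loadReference(fa), vcf)
    s <- siteTable(panel)
    ## two records, one merged site anchored at the run's first column
    expect_identical(nrow(s), 1L)
    expect_identical(s$refOffset, 2)
    expect_identical(s$ref, "CG")
    ## per-haplotype merged strings: H1 carries GT, H2 carries CT
    expect_setequal(strsplit(s$alts, ",")[[1]], c("GT", "CT"))
    m <- markerTable(panel)
    expect_identical(nrow(m), 3L)           # one mark per haplotype
    expect_identical(unique(m$refOffset), 2)
    expect_identical(sort(m$allele), c(0L, 1L, 2L))
    expect_identical(panelTextString(panel), "AACGTT#AAGTTT#AACTTT#$")
})

test_that("marked-locus count matches surviving records and is monotone in minAf", {
    d <- file.path(tempdir(), "panelcount")
    sim <- simulatePanel(11, d, chromLength = 2000L, nHaplotypes = 6L,
                         snvRate = 0.015, indelRate = 0.003)
    panel0 <- buildPanel(loadReference(sim$fasta), sim$vcf, minAf = 0)
    s <- siteTable(panel0)
    ## every generated record has >= 1 carrier, no two records abut, so with
    ## minAf = 0 each surviving record is one marked locus
    expect_identical(sum(s$marked), nrow(sim$sites))
    nMarked <- vapply(c(0, 0.05, 0.15, 0.3, 0.6),
                      function(q) sum(siteTable(buildPanel(
                          loadReference(sim$fasta), sim$vcf,
                          minAf = q))$marked), numeric(1))
    expect_true(all(diff(nMarked) <= 0))
    expect_identical(nMarked[length(nMarked)], 0)
})

test_that("haplotype splicing reproduces an independent reconstruction", {
    d <- file.path(tempdir(), "panelsplice")
    sim <- simulatePanel(13, d, chromLength = 1500L, nHaplotypes = 4L,
                         snvRate = 0.02, indelRate = 0.005)
    panel <- buildPanel(loadReference(sim$fasta), sim$vcf)
    haps <- strsplit(panelTextString(panel), "#", fixed = TRUE)[[1]]
    expect_identical(haps[1], unname(sim$ref[1]))       # T_0
    for (h in seq_len(sim$nHaplotypes)) {
        alleleStr <- ifelse(sim$hapAlleles[, h] == 1L, sim$sites$alt,
                            sim$sites$ref)
        expected <- handSplice(sim$ref[[1]], sim$sites$pos - 1L,
                               nchar(sim$sites$ref), alleleStr)
        expect_identical(haps[h + 1], expected)
    }
    ## every marker lies strictly inside its haplotype's DNA interval
    m <- markerTable(panel)
    expect_false(anyNA(markerArray:::.hapOf(panel, m$textOffset)))
})

test_that("invalid panels are rejected or skipped as specified", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"),
                            c(chrA = "ACGTACGTACGT"))
    ref <- loadReference(fa)
    ## unsorted
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=12>",
                           c("chrA\t8\t.\tT\tG\t.\tPASS\t.\tGT\t0|1",
                             "chrA\t2\t.\tC\tA\t.\tPASS\t.\tGT\t0|1"))
    expect_error(buildPanel(ref, vcf), "not sorted")
    ## unphased
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=12>",
                           "chrA\t2\t.\tC\tA\t.\tPASS\t.\tGT\t0/1")
    expect_error(buildPanel(ref, vcf), "phased")
    ## symbolic ALT is skipped with a warning; the valid record survives
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=12>",
                           c("chrA\t2\t.\tC\t<DEL>\t.\tPASS\t.\tGT\t0|1",
                             "chrA\t8\t.\tT\tG\t.\tPASS\t.\tGT\t0|1"))
    expect_warning(panel <- buildPanel(ref, vcf), "skipped")
    expect_identical(nrow(siteTable(panel)), 1L)
    expect_identical(siteTable(panel)$refOffset, 7)
    ## overlapping records: the later one is skipped
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=12>",
                           c("chrA\t2\t.\tCGT\tC\t.\tPASS\t.\tGT\t0|1",
                             "chrA\t4\t.\tT\tA\t.\tPASS\t.\tGT\t0|1"))
    expect_warning(panel <- buildPanel(ref, vcf), "overlap")
    expect_identical(nrow(siteTable(panel)), 1L)
    expect_identical(siteTable(panel)$ref, "CGT")
})

test_that("multi-allelic sites carry distinct allele numbers", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "AACCTTGG"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=8>",
                           "chrA\t4\t.\tC\tG,T\t.\tPASS\t.\tGT\t1|2",
                           samples = "S1")
    panel <- buildPanel(loadReference(fa), vcf)
    m <- markerTable(panel)
    expect_identical(sort(m$allele), c(0L, 1L, 2L))
    expect_identical(panelTextString(panel), "AACCTTGG#AACGTTGG#AACTTTGG#$")
})
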