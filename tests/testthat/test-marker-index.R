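test_that("permuteMarkers satisfies MA[i] = M[SA[i]]", {
    ## panel with no markers: empty output
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "ACGTACGT"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=8>", character(0))
    panel <- buildPanel(loadReference(fa), vcf)
    fm <- buildFMIndex(panel@text)
    expect_identical(nrow(permuteMarkers(panel, fm)), 0L)

    ## single marked SNV: non-empty exactly at rows whose SA value is a
    ## marker's text offset (invert the suffix array by hand)
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=8>",
                           "chrA\t4\t.\tT\tG\t.\tPASS\t.\tGT\t0|1")
    panel <- buildPanel(loadReference(fa), vcf)
    fm <- buildFMIndex(panel@text)
    ma <- permuteMarkers(panel, fm)
    sa <- suffixArray(fm)
    for (p in markerTable(panel)$textOffset)
        expect_true((which(sa == p) - 1L) %in% ma$row)
    expect_identical(nrow(ma), nrow(markerTable(panel)))

    ## random panel: dense definitional check at every row
    tp <- tinyPanelIndex(23)
    panel <- tp$idx@panel; fm <- tp$idx@fm
    ma <- permuteMarkers(panel, fm)
    m <- markerTable(panel)
    for (i in seq_len(nrow(ma))) {
        p <- sa <- suffixArray(fm)[ma$row[i] + 1L]
        sel <- m[m$textOffset == p, ]
        expect_true(any(sel$chrom == ma$chrom[i] &
                        sel$refOffset == ma$refOffset[i] &
                        sel$allele == ma$allele[i]))
    }
})

test_that("smearing with w = 0 reduces to the permuted marker array", {
    tp <- tinyPanelIndex(29, window = 0L)
    idx <- tp$idx
    ma <- permuteMarkers(idx@panel, idx@fm)
    dec <- decodeMarkerArray(idx@markerIndex)
    for (r in seq_len(idx@fm@n) - 1L) {
        got <- dec[[r + 1L]]
        want <- ma[ma$row == r, c("chrom", "refOffset", "allele")]
        rownames(want) <- NULL
        expect_identical(got, want[order(want$chrom, want$refOffset,
                                         want$allele), , drop = FALSE])
    }
})

test_that("a single mark smears onto the w rows to its left, clamped", {
    fa <- writeFastaFixture(tempfile(fileext = ".fa"), c(chrA = "ACGTACG"))
    vcf <- writeVcfFixture(tempfile(fileext = ".vcf"),
                           "##contig=<ID=chrA,length=7>",
                           "chrA\t4\t.\tT\tC\t.\tPASS\t.\tGT\t1")
    panel <- buildPanel(loadReference(fa), vcf)
    fm <- buildFMIndex(panel@text)
    w <- 2L
    arr <- buildMarkerIndex(panel, fm, window = w)
    sa <- suffixArray(fm)
    for (mi in seq_len(nrow(markerTable(panel)))) {
        p <- markerTable(panel)$textOffset[mi]
        h <- markerArray:::.hapOf(panel, p)
        lo <- max(p - w, panel@hapStart[h])
        carriers <- which(sa %in% lo:p) - 1L
        for (r in carriers) {
            got <- sparseAccess(arr, r)
            expect_true(any(got$refOffset == markerTable(panel)$refOffset[mi]))
        }
    }
})

test_that("decoded MA^w equals the brute-force window scan everywhere", {
    for (seed in c(31, 37)) {
        tp <- tinyPanelIndex(seed, chromLength = 250L, nHaplotypes = 4L)
        panel <- tp$idx@panel; fm <- tp$idx@fm
        for (w in c(1L, 5L, 19L)) {
            arr <- buildMarkerIndex(panel, fm, window = w)
            expect_identical(countSmearDisagreements(panel, fm, w, arr), 0L)
        }
    }
    ## one panel compared row by row with the full data-frame oracle
    tp <- tinyPanelIndex(38, chromLength = 120L, nHaplotypes = 2L)
    panel <- tp$idx@panel; fm <- tp$idx@fm
    arr <- buildMarkerIndex(panel, fm, window = 5L)
    for (r in seq_len(fm@n) - 1L) {
        got <- sparseAccess(arr, r)
        rownames(got) <- NULL
        expect_identical(got[order(got$chrom, got$refOffset, got$allele), ,
                             drop = FALSE],
                         naiveSmearedRow(panel, fm, 5L, r))
    }
})

test_that("sparse encoding detects maximal runs (hand-traced case)", {
    ## rows [empty, m, m, empty, m'] -> two runs
    m <- data.frame(chrom = 0L, refOffset = 10, allele = 1L)
    m2 <- data.frame(chrom = 0L, refOffset = 20, allele = 0L)
    entries <- rbind(cbind(row = 1L, m), cbind(row = 2L, m),
                     cbind(row = 4L, m2))
    arr <- sparseEncode(entries, n = 5L, window = 0L)
    expect_identical(numRuns(arr), 2L)
    expect_identical(arr@startPos, c(1L, 4L))
    expect_identical(arr@endPos, c(2L, 4L))
    expect_identical(nrow(arr@payload), 2L)
    expect_identical(arr@listStart, c(0L, 1L))
    ## membership and contents via the sparse-access procedure
    expect_identical(nrow(sparseAccess(arr, 0L)), 0L)
    expect_identical(sparseAccess(arr, 1L)$refOffset, 10)
    expect_identical(sparseAccess(arr, 2L)$refOffset, 10)
    expect_identical(nrow(sparseAccess(arr, 3L)), 0L)
    expect_identical(sparseAccess(arr, 4L)$refOffset, 20)
    expect_error(sparseAccess(arr, 5L), "range")

    ## adjacent rows with different lists stay separate runs
    entries2 <- rbind(cbind(row = 1L, m), cbind(row = 2L, m2))
    arr2 <- sparseEncode(entries2, n = 3L, window = 0L)
    expect_identical(numRuns(arr2), 2L)

    ## all-empty input: x = 0, payload empty, every row empty
    arr0 <- sparseEncode(entries[0, ], n = 4L, window = 0L)
    expect_identical(numRuns(arr0), 0L)
    expect_identical(nrow(arr0@payload), 0L)
    expect_identical(nrow(sparseAccess(arr0, 2L)), 0L)
})

test_that("run-length compression uses fewer runs than non-empty rows", {
    tp <- tinyPanelIndex(41, chromLength = 600L, nHaplotypes = 6L)
    arr <- tp$idx@markerIndex
    nonEmpty <- sum(vapply(seq_len(arr@n) - 1L,
                           function(r) nrow(sparseAccess(arr, r)) > 0,
                           logical(1)))
    expect_lte(numRuns(arr), nonEmpty)
    expect_gt(numRuns(arr), 0L)
})
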