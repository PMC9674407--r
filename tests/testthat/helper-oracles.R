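## Independent oracles and fixture builders shared across the suite.
## Oracles are deliberately naive (brute force) and never call the code
## paths they check.

## brute-force suffix array: sort all suffixes lexicographically using the
## package's fixed alphabet order (via a code-string transliteration so
## base-R string comparison agrees with the internal symbol order)
naiveSuffixArray <- function(text) {
    n <- nchar(text)
    key <- chartr("$#ACGNT", "1234567", text)
    sufs <- substring(key, 1:n, n)
    order(sufs, method = "radix") - 1L
}

## brute-force BWT from the naive suffix array
naiveBWT <- function(text) {
    n <- nchar(text)
    sa <- naiveSuffixArray(text)
    paste(substring(text, ((sa - 1L) %% n) + 1L, ((sa - 1L) %% n) + 1L),
          collapse = "")
}

## overlapping occurrence offsets (0-based) of pattern in text by direct scan
naiveOccurrences <- function(text, pattern) {
    n <- nchar(text); m <- nchar(pattern)
    if (m == 0L || m > n) return(integer(0))
    starts <- 1:(n - m + 1L)
    which(substring(text, starts, starts + m - 1L) == pattern) - 1L
}

## random DNA text with sentinel
randomText <- function(len) {
    paste0(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), "$")
}

## decode a panel text back to a character string
panelTextString <- function(panel) {
    markerArray:::.decodeCodes(panel@text)
}

## naive marker-overlap scan: every (occurrence offset, marker) pair where
## an occurrence of `pattern` in the panel text overlaps a dense marker
naiveMarkerOverlap <- function(index, pattern) {
    panel <- index@panel
    txt <- panelTextString(panel)
    occ <- naiveOccurrences(txt, pattern)
    m <- panel@markers
    hits <- lapply(occ, function(p) {
        sel <- m$textOffset >= p & m$textOffset < p + nchar(pattern)
        if (!any(sel)) return(NULL)
        data.frame(offset = p, chrom = m$chrom[sel],
                   refOffset = m$refOffset[sel], allele = m$allele[sel])
    })
    out <- do.call(rbind, Filter(Negate(is.null), hits))
    if (is.null(out))
        out <- data.frame(offset = integer(0), chrom = integer(0),
                          refOffset = numeric(0), allele = integer(0))
    out <- unique(out)
    out <- out[order(out$offset, out$chrom, out$refOffset, out$allele), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

## brute-force MA^w: for each row, markers of the dense array at text
## offsets SA[row] .. SA[row] + w, truncated at the end of the containing
## haplotype, sorted the way the package sorts lists
naiveSmearedRow <- function(panel, fm, w, row) {
    s <- fm@sa[row + 1L]
    h <- markerArray:::.hapOf(panel, s)
    empty <- data.frame(chrom = integer(0), refOffset = numeric(0),
                        allele = integer(0))
    if (is.na(h)) return(empty)
    hapEnd <- panel@hapStart[h] + panel@hapLen[h] - 1L
    lo <- s; hi <- min(s + w, hapEnd)
    m <- panel@markers
    sel <- m$textOffset >= lo & m$textOffset <= hi
    out <- m[sel, c("chrom", "refOffset", "allele"), drop = FALSE]
    out <- out[order(out$chrom, out$refOffset, out$allele), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## count rows where the sparse-encoded MA^w disagrees with a brute-force
## dense window scan (key-vector form of naiveSmearedRow, kept fast so the
## 200-panel acceptance check fits its time budget); also verifies the
## rank-based membership test against dense emptiness at every row
countSmearDisagreements <- function(panel, fm, w, arr) {
    m <- panel@markers
    mKeys <- paste(m$chrom, m$refOffset, m$allele)
    lookup <- vector("list", fm@n)
    if (nrow(m)) {
        byOffset <- split(seq_len(nrow(m)), m$textOffset)
        lookup[as.integer(names(byOffset)) + 1L] <- byOffset
    }
    hapEnd <- panel@hapStart + panel@hapLen - 1L
    bad <- 0L
    for (r in seq_len(fm@n) - 1L) {
        s <- fm@sa[r + 1L]
        h <- markerArray:::.hapOf(panel, s)
        want <- if (is.na(h)) character(0) else {
            idx <- unlist(lookup[(s + 1L):(min(s + w, hapEnd[h]) + 1L)],
                          use.names = FALSE)
            sort(mKeys[idx])
        }
        got <- sparseAccess(arr, r)
        gotK <- sort(paste(got$chrom, got$refOffset, got$allele))
        member <- markerArray:::.rank1(arr@startPos, r + 1L) >
            markerArray:::.rank1(arr@endPos, r)
        if (!identical(unname(gotK), unname(want)) ||
            !identical(member, length(want) > 0L))
            bad <- bad + 1L
    }
    bad
}

## tiny simulated panel + index, for randomized property tests
tinyPanelIndex <- function(seed, chromLength = 400L, nHaplotypes = 4L,
                           snvRate = 0.02, indelRate = 0.005,
                           window = 19L, minAf = 0, saSampleRate = 4L) {
    d <- file.path(tempdir(), paste0("tinypanel", seed))
    sim <- simulatePanel(seed, d, chromLength = chromLength,
                         nHaplotypes = nHaplotypes, snvRate = snvRate,
                         indelRate = indelRate, maxIndelLen = 4L)
    idx <- buildPanelIndex(sim$fasta, sim$vcf, window = window,
                           minAf = minAf, saSampleRate = saSampleRate)
    list(sim = sim, idx = idx)
}

## write a handcrafted single-sample-or-more VCF
writeVcfFixture <- function(path, chromLines, bodyLines,
                            samples = c("S1")) {
    hdr <- c("##fileformat=VCFv4.2", chromLines,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, bodyLines), path)
    path
}

## write a small FASTA
writeFastaFixture <- function(path, seqs) {
    writeLines(unlist(lapply(names(seqs), function(nm)
        c(paste0(">", nm), seqs[[nm]]))), path)
    path
}
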