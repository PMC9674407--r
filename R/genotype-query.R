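## Read genotyping: the heuristic backward-search loop over MA^w, plus the
## exact FL-stepping and locate-based marker queries used as oracles.

## ---- exact marker queries -------------------------------------------------

## markers (data.frame sorted by textOffset) overlapping text span [lo, hi)
.markersInSpan <- function(markers, lo, hi) {
    if (nrow(markers) == 0L) return(NULL)
    i1 <- findInterval(lo - 1, markers$textOffset) + 1L
    i2 <- findInterval(hi - 1, markers$textOffset)
    if (i1 > i2) return(NULL)
    markers[i1:i2, , drop = FALSE]
}

## expand a vector of visited rows into the MA entries sitting at them;
## maRows is sorted by row and may hold several markers per row
.maAtRows <- function(maRows, vr, occOffset) {
    if (nrow(maRows) == 0L) return(NULL)
    urows <- unique(maRows$row)
    ustart <- match(urows, maRows$row)
    ulen <- c(diff(ustart), nrow(maRows) - ustart[length(ustart)] + 1L)
    j <- match(vr, urows)
    hit <- which(!is.na(j))
    if (length(hit) == 0L) return(NULL)
    j <- j[hit]
    idx <- rep(ustart[j], ulen[j]) + sequence(ulen[j]) - 1L
    qi <- rep(hit, ulen[j])
    data.frame(offset = occOffset[qi],
               chrom = maRows$chrom[idx],
               refOffset = maRows$refOffset[idx],
               allele = maRows$allele[idx])
}

.sortMarkerHits <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
        return(data.frame(offset = integer(0), chrom = integer(0),
                          refOffset = numeric(0), allele = integer(0)))
    df <- unique(df)
    df <- df[order(df$offset, df$chrom, df$refOffset, df$allele), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Exact marker query by FL stepping
#'
#' Finds the maximal suffix-array range for the whole pattern by backward
#' search, then walks `|q| - 1` FL steps from every row in the range,
#' collecting the suffix-rank-ordered marker array MA at each visited row.
#' Returns every marker overlapped by an occurrence of the pattern,
#' together with the occurrence's text offset.
#'
#' @param pattern Non-empty DNA string.
#' @param index A [PanelIndex-class].
#' @return `data.frame` (`offset`, `chrom`, `refOffset`, `allele`): one row
#'   per (occurrence, overlapped marker) pair; zero rows if the pattern does
#'   not occur.
#' @export
flMarkerQuery <- function(pattern, index) {
    if (!nzchar(pattern)) stop("pattern must be non-empty")
    fm <- index@fm
    r <- patternRange(fm, pattern)
    if (r[1L] == r[2L]) return(.sortMarkerHits(NULL))
    rows0 <- seq(r[1L], r[2L] - 1L)
    occOffset <- fm@sa[rows0 + 1L]
    m <- nchar(pattern)
    hits <- list(.maAtRows(index@maRows, rows0, occOffset))
    rs <- rows0
    if (m > 1L) for (t in seq_len(m - 1L)) {
        rs <- flStep(fm, rs)
        hits[[t + 1L]] <- .maAtRows(index@maRows, rs, occOffset)
    }
    .sortMarkerHits(do.call(rbind, Filter(Negate(is.null), hits)))
}

#' Exact marker query by locate + dense lookup
#'
#' The alternate strategy: after backward search, each row in the range is
#' resolved to a text offset with the sampled suffix array, and the dense
#' marker array M is scanned over the occurrence's span. Must agree exactly
#' with [flMarkerQuery()].
#'
#' @inheritParams flMarkerQuery
#' @return As [flMarkerQuery()].
#' @export
locateMarkerQuery <- function(pattern, index) {
    if (!nzchar(pattern)) stop("pattern must be non-empty")
    fm <- index@fm
    r <- patternRange(fm, pattern)
    if (r[1L] == r[2L]) return(.sortMarkerHits(NULL))
    m <- nchar(pattern)
    markers <- index@panel@markers
    hits <- lapply(seq(r[1L], r[2L] - 1L), function(x) {
        p <- locateRow(fm, x)
        sp <- .markersInSpan(markers, p, p + m)
        if (is.null(sp)) return(NULL)
        data.frame(offset = p, chrom = sp$chrom, refOffset = sp$refOffset,
                   allele = sp$allele)
    })
    .sortMarkerHits(do.call(rbind, Filter(Negate(is.null), hits)))
}

## ---- the heuristic genotyping loop ----------------------------------------

## One strand of one read. Proceeds right to left; on a failed extension the
## range resets to [0, n) and matching restarts at the next character. Every
## w successful steps, if the range width is at most Nh, the smeared marker
## array is queried over the range and (site, allele) observations tallied.
## When an extension ends, a final sub-window query is made if 0 < k < w so
## alleles near the read's 5' end are not dropped, and the extension's
## evidence is kept only if it has no conflicting alleles at a site, touches
## a single chromosome, and matched at least minSeedLen characters.
.genotypeStrand <- function(codes, fm, arr, Nh, w, minSeedLen, strand) {
    n <- fm@n
    C <- fm@cArr
    occ <- fm@occ
    lo <- 0L; hi <- n
    l <- 0L; k <- 0L
    tal <- list(); tn <- 0L
    evs <- list(); ne <- 0L
    best <- 0L

    finishExtension <- function() {
        if (l == 0L) return(invisible())
        if (l > best) best <<- l
        if (l >= minSeedLen) {
            if (k > 0L && hi - lo <= Nh) {        # leftover window query
                mk <- .rangeMarkers(arr, lo, hi)
                if (!is.null(mk)) { tn <<- tn + 1L; tal[[tn]] <<- mk }
            }
            if (tn > 0L) {
                m <- unique(do.call(rbind, tal[seq_len(tn)]))
                key <- paste(m$chrom, m$refOffset)
                if (!anyDuplicated(key) && length(unique(m$chrom)) == 1L) {
                    ne <<- ne + 1L
                    evs[[ne]] <<- list(sites = m, matchLen = l,
                                       strand = strand)
                }
            }
        }
        invisible()
    }

    for (o in rev(seq_along(codes))) {
        cc <- codes[o]
        ok <- !is.na(cc) && (cc == 3L || cc == 4L || cc == 5L || cc == 7L)
        if (ok) {
            nl <- C[cc] + occ[lo + 1L, cc]
            nh <- C[cc] + occ[hi + 1L, cc]
            ok <- nl < nh
        }
        if (!ok) {
            finishExtension()
            lo <- 0L; hi <- n; l <- 0L; k <- 0L
            tal <- list(); tn <- 0L
        } else {
            lo <- nl; hi <- nh
            l <- l + 1L; k <- k + 1L
            if (k == w) {
                if (hi - lo <= Nh) {
                    mk <- .rangeMarkers(arr, lo, hi)
                    if (!is.null(mk)) { tn <- tn + 1L; tal[[tn]] <- mk }
                }
                k <- 0L                            # query every w steps
            }
        }
    }
    finishExtension()
    list(evidence = evs, best = best)
}

#' Genotype a single read against a panel index
#'
#' Runs the heuristic backward-search loop: the read is processed right to
#' left, restarting at the next character whenever the suffix-array range
#' empties; every `w` successful steps the smeared marker array is queried,
#' provided the range is no wider than the number of haplotypes in the
#' index. An extension's evidence is discarded wholesale if any site is
#' observed with conflicting alleles, the touched sites span more than one
#' chromosome, or fewer than `minSeedLen` characters matched. A random
#' initial strand is investigated first; if its best extension reaches
#' `minSeedLen` the other strand is skipped, otherwise both strands'
#' evidence is finalized independently. Characters outside \{A,C,G,T\}
#' (including `N`) terminate the current extension.
#'
#' @param read DNA string.
#' @param index A [PanelIndex-class].
#' @param minSeedLen Minimum matched length for an extension's evidence to
#'   count (default 80).
#' @return List of finalized extension evidence; each element has `sites`
#'   (`data.frame` `chrom`, `refOffset`, `allele`; one observation per site
#'   per extension), `matchLen`, and `strand` (`"+"` or `"-"`).
#' @export
genotypeRead <- function(read, index, minSeedLen = 80L) {
    if (!nzchar(read)) return(list())
    fm <- index@fm
    arr <- index@markerIndex
    Nh <- index@panel@hapCount
    w <- index@window
    fwd <- .encodeChars(toupper(read))
    rc <- .revcompCodes(fwd)
    ord <- if (stats::runif(1L) < 0.5) c("+", "-") else c("-", "+")
    firstCodes <- if (ord[1L] == "+") fwd else rc
    r1 <- .genotypeStrand(firstCodes, fm, arr, Nh, w, minSeedLen, ord[1L])
    if (r1$best >= minSeedLen) return(r1$evidence)
    secondCodes <- if (ord[2L] == "+") fwd else rc
    r2 <- .genotypeStrand(secondCodes, fm, arr, Nh, w, minSeedLen, ord[2L])
    c(r1$evidence, r2$evidence)
}

#' Accumulate finalized evidence into an evidence table
#'
#' For each surviving extension and site, increments the count of the
#' observed allele (allele 0 contributes to the reference count `l`; the
#' total over all alleles at a site is `k`).
#'
#' @param evidenceList List of evidence as returned by [genotypeRead()].
#' @param table An [EvidenceTable-class] to add to (default empty).
#' @return An updated [EvidenceTable-class].
#' @export
accumulateEvidence <- function(evidenceList, table = emptyEvidenceTable()) {
    if (length(evidenceList) == 0L) return(table)
    df <- do.call(rbind, lapply(evidenceList, `[[`, "sites"))
    df$count <- 1L
    df <- rbind(table@counts, df[, c("chrom", "refOffset", "allele", "count")])
    agg <- stats::aggregate(count ~ chrom + refOffset + allele, df, sum)
    agg <- agg[order(agg$chrom, agg$refOffset, agg$allele), , drop = FALSE]
    rownames(agg) <- NULL
    methods::new("EvidenceTable", counts = agg, nReads = table@nReads,
                 nExtensions = table@nExtensions +
                     as.integer(length(evidenceList)))
}

#' Genotype a set of reads
#'
#' Applies [genotypeRead()] to every read and aggregates the surviving
#' evidence into per-site allele counts. Base qualities are ignored by the
#' matching core.
#'
#' @param reads A character vector of read sequences, a `DNAStringSet`, or
#'   the path to a FASTQ file (gzip transparent).
#' @param index A [PanelIndex-class].
#' @param minSeedLen Minimum matched length per extension (default 80).
#' @param seed Optional integer seed driving the random strand choice; fixed
#'   seeds make the output bit-identical across runs.
#' @return An [EvidenceTable-class].
#' @export
genotypeReads <- function(reads, index, minSeedLen = 80L, seed = NULL) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    if (methods::is(reads, "XStringSet"))
        reads <- as.character(reads)
    if (!is.null(seed)) set.seed(seed)
    allEv <- vector("list", length(reads))
    for (i in seq_along(reads))
        allEv[[i]] <- genotypeRead(reads[i], index, minSeedLen)
    tab <- accumulateEvidence(do.call(c, allEv))
    tab@nReads <- length(reads)
    tab
}
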