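## Panel construction: reference FASTA + phased VCF -> concatenated pangenome
## text T, dense marker array M, edit table E.
##
## Conventions:
##  * internal offsets are 0-based; VCF POS is 1-based and converted on read;
##  * a site's "anchor" is the first reference base of its REF span: for
##    substitutions that is the first substituted column, for left-anchored
##    indels it is the base just to the left of the inserted/deleted bases,
##    so suffixes starting at the marked position include the allele itself;
##  * the allele-frequency of a site is computed over all panel haplotypes
##    plus the reference T_0 (which always carries allele 0); a site is
##    marked iff its minor-allele frequency strictly exceeds `minAf`.

## ---- VCF parsing ----------------------------------------------------------

.readPanelVcf <- function(vcfPath, refNames, excludeSamples = character(0)) {
    if (!file.exists(vcfPath))
        stop("VCF file not found: ", vcfPath)
    vcf <- VariantAnnotation::readVcf(vcfPath, genome = "panel")
    rr <- SummarizedExperiment::rowRanges(vcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop("VCF has no GT field")
    if (ncol(gt) == 0L)
        stop("VCF has no samples")
    keep <- !(colnames(gt) %in% excludeSamples)
    if (!any(keep))
        stop("all samples excluded")
    gt <- gt[, keep, drop = FALSE]
    altL <- as.list(as(VariantAnnotation::alt(vcf), "CharacterList"))
    list(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = BiocGenerics::start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alts = altL,
        gt = gt,
        samples = colnames(gt)
    )
}

## Split "a|b" GT strings into a haplotype allele matrix (records x haps).
## Errors on unphased or missing genotypes; haploid "a" contributes one
## haplotype, diploid "a|b" two.
.expandHaplotypes <- function(gt, samples) {
    nrec <- nrow(gt)
    if (any(grepl("/", gt, fixed = TRUE)))
        stop("unphased genotype in VCF (found '/'); panel must be phased")
    if (any(grepl(".", gt, fixed = TRUE)))
        stop("missing genotype ('.') in VCF; panel must be fully genotyped")
    if (nrec == 0L) {
        ## no records: ploidy is unknowable; assume diploid samples
        hapNames <- as.vector(t(outer(samples, 1:2, paste, sep = "_")))
        return(list(alleles = matrix(integer(0), 0L, length(hapNames)),
                    hapNames = hapNames))
    }
    ploidy <- lengths(strsplit(gt[1L, ], "|", fixed = TRUE))
    cols <- lapply(seq_along(samples), function(j) {
        parts <- strsplit(gt[, j], "|", fixed = TRUE)
        if (any(lengths(parts) != ploidy[j]))
            stop("inconsistent ploidy for sample ", samples[j])
        m <- matrix(suppressWarnings(as.integer(unlist(parts))),
                    nrow = nrec, byrow = TRUE)
        if (anyNA(m))
            stop("non-numeric allele in GT for sample ", samples[j])
        m
    })
    hapNames <- unlist(lapply(seq_along(samples), function(j) {
        if (ploidy[j] == 1L) samples[j]
        else paste(samples[j], seq_len(ploidy[j]), sep = "_")
    }))
    list(alleles = do.call(cbind, cols), hapNames = hapNames)
}

## ---- record validation and site construction ------------------------------

## Validates records in file order, skipping (with a warning) records that
## overlap a kept record, carry symbolic or malformed alleles, or have more
## than 15 alternates. Unsorted records are an error.
.validateRecords <- function(v, refNames, refLens, alleleMat) {
    nrec <- length(v$pos)
    keep <- logical(nrec)
    dropMsg <- character(0)
    lastEnd <- stats::setNames(rep(-1, length(refNames)), refNames)
    lastPos <- stats::setNames(rep(-Inf, length(refNames)), refNames)
    for (i in seq_len(nrec)) {
        ch <- v$chrom[i]
        if (!(ch %in% refNames))
            stop("VCF chromosome not in reference FASTA: ", ch)
        p0 <- v$pos[i] - 1                     # 0-based anchor
        rl <- nchar(v$ref[i])
        if (v$pos[i] < lastPos[ch])
            stop("VCF is not sorted (chromosome ", ch, ", position ",
                 v$pos[i], ")")
        lastPos[ch] <- v$pos[i]
        alts <- v$alts[[i]]
        bad <- NULL
        if (length(alts) == 0L) bad <- "no ALT allele"
        else if (length(alts) > 15L) bad <- "more than 15 alternate alleles"
        else if (any(grepl("[<>\\[\\]*]", alts))) bad <- "symbolic ALT allele"
        else if (any(grepl("[^ACGTN]", toupper(alts))) ||
                 grepl("[^ACGTN]", toupper(v$ref[i]))) bad <- "malformed allele"
        else if (p0 + rl > refLens[ch]) bad <- "REF span beyond chromosome end"
        else if (p0 <= lastEnd[ch]) bad <- "overlaps previous record"
        else if (max(alleleMat[i, ]) > length(alts))
            stop("GT allele index exceeds ALT count at ", ch, ":", v$pos[i])
        if (is.null(bad)) {
            keep[i] <- TRUE
            lastEnd[ch] <- p0 + rl - 1
        } else {
            dropMsg <- c(dropMsg, paste0(ch, ":", v$pos[i], " (", bad, ")"))
        }
    }
    if (length(dropMsg))
        warning("skipped ", length(dropMsg), " VCF record(s): ",
                paste(utils::head(dropMsg, 5L), collapse = "; "),
                if (length(dropMsg) > 5L) " ...")
    keep
}

## Merge maximal runs of abutting pure-substitution records into single
## sites (consecutive substituted columns collapse into one edit); all other
## records map to one site each. Returns a list of per-site descriptors.
.recordsToSites <- function(v, alleleMat, chromIdx) {
    nrec <- length(v$pos)
    if (nrec == 0L) return(list())
    refLen <- nchar(v$ref)
    isSub <- vapply(seq_len(nrec), function(i)
        all(nchar(v$alts[[i]]) == refLen[i]), logical(1))
    ## run id: start a new site unless this record abuts a previous
    ## substitution record on the same chromosome and is itself one
    runId <- integer(nrec)
    cur <- 0L
    for (i in seq_len(nrec)) {
        newRun <- TRUE
        if (i > 1L && isSub[i] && isSub[i - 1L] &&
            v$chrom[i] == v$chrom[i - 1L] &&
            v$pos[i] == v$pos[i - 1L] + refLen[i - 1L])
            newRun <- FALSE
        if (newRun) cur <- cur + 1L
        runId[i] <- cur
    }
    nhap <- ncol(alleleMat)
    lapply(split(seq_len(nrec), runId), function(ix) {
        ch <- v$chrom[ix[1L]]
        p0 <- v$pos[ix[1L]] - 1
        refStr <- paste(v$ref[ix], collapse = "")
        if (length(ix) == 1L) {
            alts <- v$alts[[ix]]
            hapAll <- alleleMat[ix, ]
        } else {
            ## per-haplotype concatenated strings across the merged columns
            perHap <- vapply(seq_len(nhap), function(h) {
                paste(vapply(ix, function(i) {
                    a <- alleleMat[i, h]
                    if (a == 0L) v$ref[i] else v$alts[[i]][a]
                }, character(1)), collapse = "")
            }, character(1))
            alts <- unique(perHap[perHap != refStr])
            hapAll <- match(perHap, alts, nomatch = 0L)
        }
        list(chrom = chromIdx[ch], chromName = ch, refOffset = p0,
             ref = refStr, alts = toupper(alts),
             refLen = nchar(refStr), hapAlleles = as.integer(hapAll))
    })
}

.classifyEdit <- function(ref, alt) {
    if (nchar(ref) == nchar(alt)) {
        c(type = "sub", value = alt)
    } else if (nchar(alt) > nchar(ref) && nchar(ref) == 1L &&
               substr(alt, 1L, 1L) == ref) {
        c(type = "ins", value = substr(alt, 2L, nchar(alt)))
    } else if (nchar(ref) > nchar(alt) && nchar(alt) == 1L &&
               substr(ref, 1L, 1L) == alt) {
        c(type = "del", value = as.character(nchar(ref) - 1L))
    } else {
        ## non-canonical length change: keep as a generic replacement
        c(type = "sub", value = alt)
    }
}

## ---- haplotype splicing ---------------------------------------------------

## Splice one chromosome of one haplotype. `sites` is the site list for this
## chromosome in position order; `alleles` the haplotype's allele index per
## site. Returns the spliced sequence and the 0-based local offset of every
## site's anchor within it.
.spliceChrom <- function(refSeq, sites, alleles) {
    if (length(sites) == 0L)
        return(list(seq = refSeq, anchors = numeric(0)))
    p0 <- vapply(sites, `[[`, numeric(1), "refOffset")
    rl <- vapply(sites, `[[`, numeric(1), "refLen")
    alleleStr <- vapply(seq_along(sites), function(i) {
        a <- alleles[i]
        if (a == 0L) sites[[i]]$ref else sites[[i]]$alts[a]
    }, character(1))
    gapStart <- c(0, p0 + rl)                  # 0-based
    gapEnd <- c(p0, nchar(refSeq))             # half-open
    gaps <- substring(refSeq, gapStart + 1, gapEnd)
    nSites <- length(sites)
    pieces <- character(2L * nSites + 1L)
    pieces[seq(1L, 2L * nSites + 1L, by = 2L)] <- gaps
    pieces[seq(2L, 2L * nSites, by = 2L)] <- alleleStr
    lens <- nchar(pieces)
    before <- cumsum(lens)
    ## anchor of site i sits right after gap i: cumulative length of pieces
    ## 1 .. 2i-1
    anchors <- before[seq(1L, 2L * nSites, by = 2L)]
    list(seq = paste(pieces, collapse = ""), anchors = anchors)
}

## ---- main builder ---------------------------------------------------------

#' Build a concatenated haplotype panel from a reference and a phased VCF
#'
#' Produces the pangenome text \eqn{T} (reference haplotype `T_0` first,
#' then every sample haplotype, each terminated by a separator and the whole
#' text by a sentinel), the dense marker array (one marker per haplotype per
#' polymorphic column passing the frequency filter; allele 0 for reference
#' carriers), and the edit table. Alleles at sites that fail the frequency
#' filter are still spliced into the haplotype sequences; they just carry no
#' markers. Indel markers sit on the base just left of the indel; runs of
#' abutting substitution records collapse into a single site.
#'
#' @param reference Named character vector from [loadReference()] (or a
#'   `DNAStringSet`).
#' @param vcfPath Path to a sorted, phased, multi-sample VCF.
#' @param minAf Minimum minor-allele frequency: a site is marked iff the
#'   frequency of its less common allele, computed over all haplotypes
#'   including `T_0`, strictly exceeds `minAf`.
#' @param excludeSamples Sample names to drop before building (e.g. a
#'   held-out donor).
#' @return A [MarkerPanel-class].
#' @export
buildPanel <- function(reference, vcfPath, minAf = 0,
                       excludeSamples = character(0)) {
    if (methods::is(reference, "DNAStringSet"))
        reference <- stats::setNames(as.character(reference), names(reference))
    if (is.null(names(reference)) || anyDuplicated(names(reference)))
        stop("reference must be a named vector with unique chromosome names")
    if (minAf < 0 || minAf > 1) stop("minAf must be in [0, 1]")
    refNames <- names(reference)
    refLens <- stats::setNames(nchar(reference), refNames)
    chromIdx <- stats::setNames(seq_along(refNames) - 1L, refNames)

    v <- .readPanelVcf(vcfPath, refNames, excludeSamples)
    hap <- .expandHaplotypes(v$gt, v$samples)
    nPanelHaps <- length(hap$hapNames)

    keep <- if (length(v$pos)) {
        .validateRecords(v, refNames, refLens, hap$alleles)
    } else logical(0)
    v$chrom <- v$chrom[keep]; v$pos <- v$pos[keep]
    v$ref <- toupper(v$ref[keep]); v$alts <- v$alts[keep]
    alleleMat <- hap$alleles[keep, , drop = FALSE]

    sites <- .recordsToSites(v, alleleMat, chromIdx)

    ## allele frequency over panel haplotypes + T_0 (always reference)
    Nh <- nPanelHaps + 1L
    marked <- vapply(sites, function(s) {
        if (length(s$alts) > 15L) return(FALSE)   # >15 merged alleles: unmarked
        counts <- tabulate(s$hapAlleles + 1L, nbins = length(s$alts) + 1L)
        counts[1L] <- counts[1L] + 1L              # T_0 carries allele 0
        (1 - max(counts) / Nh) > minAf
    }, logical(1))
    over15 <- vapply(sites, function(s) length(s$alts) > 15L, logical(1))
    if (any(over15))
        warning(sum(over15), " merged site(s) exceed 15 alleles; left unmarked")

    ## edit table: distinct operations get dense ids from 1
    editKey <- character(0)
    editType <- character(0); editValue <- character(0)
    siteEditIds <- vector("list", length(sites))
    for (i in seq_along(sites)) {
        s <- sites[[i]]
        ids <- integer(length(s$alts))
        for (a in seq_along(s$alts)) {
            e <- .classifyEdit(s$ref, s$alts[a])
            key <- paste0(e[["type"]], ":", e[["value"]])
            j <- match(key, editKey)
            if (is.na(j)) {
                editKey <- c(editKey, key)
                editType <- c(editType, e[["type"]])
                editValue <- c(editValue, e[["value"]])
                j <- length(editKey)
            }
            ids[a] <- j
        }
        siteEditIds[[i]] <- ids
    }

    ## per-chromosome site lists, position order
    siteChrom <- vapply(sites, function(s) s$chromName, character(1))
    siteOrd <- order(match(siteChrom, refNames),
                     vapply(sites, `[[`, numeric(1), "refOffset"))
    sites <- sites[siteOrd]
    siteEditIds <- siteEditIds[siteOrd]
    marked <- marked[siteOrd]
    siteChrom <- siteChrom[siteOrd]
    byChrom <- split(seq_along(sites), factor(siteChrom, levels = refNames))

    ## splice every haplotype (T_0 = all-reference alleles)
    hapNames <- c("REF", hap$hapNames)
    nHaps <- length(hapNames)
    hapSeqs <- character(nHaps)
    markerRows <- vector("list", nHaps)
    for (h in seq_len(nHaps)) {
        segs <- character(length(refNames))
        chromStart <- 0
        mk <- list()
        for (ci in seq_along(refNames)) {
            ix <- byChrom[[ci]]
            alleles <- if (h == 1L || length(ix) == 0L) {
                rep(0L, length(ix))
            } else {
                vapply(sites[ix], function(s) s$hapAlleles[h - 1L], integer(1))
            }
            sp <- .spliceChrom(reference[[ci]], sites[ix], alleles)
            segs[ci] <- sp$seq
            if (length(ix)) {
                mkd <- marked[ix]
                if (any(mkd)) {
                    mk[[length(mk) + 1L]] <- data.frame(
                        localOffset = chromStart + sp$anchors[mkd],
                        chrom = chromIdx[[refNames[ci]]],
                        refOffset = vapply(sites[ix][mkd], `[[`, numeric(1),
                                           "refOffset"),
                        allele = alleles[mkd])
                }
            }
            chromStart <- chromStart + nchar(sp$seq)
        }
        hapSeqs[h] <- paste(segs, collapse = "")
        markerRows[h] <- list(if (length(mk)) do.call(rbind, mk) else NULL)
    }

    hapLen <- nchar(hapSeqs)
    hapStart <- cumsum(c(0L, utils::head(hapLen + 1L, -1L)))  # +1 separator
    text <- .encodeChars(paste0(paste0(hapSeqs, collapse = "#"), "#$"))
    stopifnot(!anyNA(text))

    mlist <- Filter(Negate(is.null), lapply(seq_len(nHaps), function(h) {
        m <- markerRows[[h]]
        if (is.null(m)) return(NULL)
        m$textOffset <- as.integer(hapStart[h] + m$localOffset)
        m
    }))
    markers <- if (length(mlist)) {
        m <- do.call(rbind, mlist)
        m <- m[order(m$textOffset), , drop = FALSE]
        data.frame(textOffset = as.integer(m$textOffset),
                   chrom = as.integer(m$chrom),
                   refOffset = as.numeric(m$refOffset),
                   allele = as.integer(m$allele))
    } else {
        data.frame(textOffset = integer(0), chrom = integer(0),
                   refOffset = numeric(0), allele = integer(0))
    }
    rownames(markers) <- NULL

    edits <- data.frame(id = seq_along(editKey), type = editType,
                        value = editValue)
    sitesDf <- data.frame(
        chrom = vapply(sites, function(s) as.integer(s$chrom), integer(1)),
        refOffset = vapply(sites, `[[`, numeric(1), "refOffset"),
        refLen = vapply(sites, `[[`, numeric(1), "refLen"),
        ref = vapply(sites, `[[`, character(1), "ref"),
        alts = vapply(sites, function(s) paste(s$alts, collapse = ","),
                      character(1)),
        editIds = vapply(siteEditIds, paste, character(1), collapse = ","),
        marked = marked
    )
    if (nrow(sitesDf) == 0L)
        sitesDf <- data.frame(chrom = integer(0), refOffset = numeric(0),
                              refLen = numeric(0), ref = character(0),
                              alts = character(0), editIds = character(0),
                              marked = logical(0))

    methods::new("MarkerPanel",
        text = text,
        hapNames = hapNames,
        hapStart = as.integer(hapStart),
        hapLen = as.integer(hapLen),
        hapCount = as.integer(nHaps),
        markers = markers,
        edits = edits,
        sites = sitesDf,
        refNames = refNames,
        refLens = as.integer(refLens),
        minAf = minAf,
        samples = v$samples)
}

## haplotype DNA interval [start, start+len) containing a text offset,
## or NA if the offset sits on a separator/sentinel
.hapOf <- function(panel, offset) {
    h <- findInterval(offset, panel@hapStart)
    inside <- h >= 1L & offset < panel@hapStart[h] + panel@hapLen[h]
    h[!inside] <- NA_integer_
    h
}
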