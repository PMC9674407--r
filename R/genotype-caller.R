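## Diploid genotype likelihoods and per-site calls.
##
## The likelihood of g reference-allele copies (g in {0,1,2}) given l
## reference observations out of k total at a site, with sequencing error
## rate eps, is
##
##   L(g) = (1/2^k) * [(2-g)eps + g(1-eps)]^l * [(2-g)(1-eps) + g*eps]^(k-l)
##
## computed here as ((a/2)^l) * ((b/2)^(k-l)) with a and b the two bracket
## terms: both bases lie in [0, 1], so there is no intermediate overflow and
## no underflow beyond the true value's own range, and the heterozygous
## likelihood L(1) = 2^-k is exact in floating point (a = b = 1).

#' Genotype likelihood under the diploid error model
#'
#' @param g Number of reference-allele copies: 0 (homozygous alternate),
#'   1 (heterozygous) or 2 (homozygous reference). Vectorised.
#' @param l Number of reference-allele observations at the site.
#' @param k Total allele observations (reference + alternate) at the site.
#' @param eps Per-base sequencing error rate in `[0, 1]`; 0 and 1 are
#'   admitted for analytic edge cases. Default 0.01.
#' @return Numeric likelihood(s) in `[0, 1]`. `L(1)` equals `2^-k` exactly
#'   for every `l` and `eps`.
#' @examples
#' genotypeLikelihood(1, 3, 4)            # 1/16
#' genotypeLikelihood(2, 10, 10, 0.01)    # 0.99^10
#' @export
genotypeLikelihood <- function(g, l, k, eps = 0.01) {
    if (any(l > k) || any(l < 0) || any(k < 0)) stop("need 0 <= l <= k")
    if (any(eps < 0) || any(eps > 1)) stop("eps must be in [0, 1]")
    if (any(!(g %in% c(0, 1, 2)))) stop("g must be 0, 1 or 2")
    a <- (2 - g) * eps + g * (1 - eps)
    b <- (2 - g) * (1 - eps) + g * eps
    (a / 2)^l * (b / 2)^(k - l)       # 0^0 == 1 covers the eps in {0,1} edges
}

## log10 genotype likelihoods for VCF GL output, computed in log space;
## 0 * log(0) terms (no observations of an impossible allele) contribute 0
.log10Lik <- function(g, l, k, eps) {
    a <- (2 - g) * eps + g * (1 - eps)
    b <- (2 - g) * (1 - eps) + g * eps
    t1 <- l * log10(a / 2)
    t2 <- (k - l) * log10(b / 2)
    t1[is.nan(t1)] <- 0
    t2[is.nan(t2)] <- 0
    t1 + t2
}

#' Call a diploid genotype from per-site counts
#'
#' Picks `g_max = argmax_g L(g)`; ties break toward larger `g` (more
#' reference copies), consistent with the haploid tie rule that prefers the
#' reference allele.
#'
#' @param l Reference-allele observations.
#' @param k Total observations (`k >= 1`; `k = 0` is a no-call and an error
#'   here — callers should omit such sites).
#' @param eps Sequencing error rate; default 0.01.
#' @return List with `g` (0, 1 or 2 reference copies), `likelihoods`
#'   (numeric triple `L(0), L(1), L(2)`), `GL` (log10 triple), `l`, `k`.
#' @export
callDiploid <- function(l, k, eps = 0.01) {
    if (k < 1L) stop("k must be >= 1 (no-call sites are omitted upstream)")
    lik <- genotypeLikelihood(c(0, 1, 2), l, k, eps)
    g <- 3L - which.max(rev(lik))     # first max of (L2, L1, L0): larger g wins
    list(g = g, likelihoods = lik, GL = .log10Lik(c(0, 1, 2), l, k, eps),
         l = l, k = k)
}

#' Call a haploid allele from per-site counts
#'
#' Majority vote between reference and alternate observations; an exact tie
#' calls the reference allele.
#'
#' @inheritParams callDiploid
#' @return `"ref"` if `l >= k - l`, else `"alt"`.
#' @export
callHaploid <- function(l, k) {
    if (k < 1L) stop("k must be >= 1 (no-call sites are omitted upstream)")
    if (l >= k - l) "ref" else "alt"
}

#' Call genotypes at every marked site with evidence
#'
#' Joins the evidence table to the panel's marked sites and produces one
#' call per site with at least one observation (`k >= 1`); sites without
#' evidence are omitted (no-call). At multi-allelic sites the most frequent
#' alternate allele (smallest index on ties) is reported as the call's ALT;
#' the likelihood model itself only distinguishes reference from
#' non-reference, as `l` and `k` do.
#'
#' @param evidence An [EvidenceTable-class].
#' @param index A [PanelIndex-class] (or [MarkerPanel-class]).
#' @param eps Sequencing error rate for the diploid model; default 0.01.
#' @param ploidy `"diploid"` (genotype likelihoods) or `"haploid"`
#'   (majority vote).
#' @return `data.frame` with one row per called site: `chrom` (0-based
#'   index), `chromName`, `refOffset` (0-based anchor), `ref`, `alts`
#'   (comma-joined panel ALTs), `topAlt` (1-based ALT index reported in the
#'   genotype), `l`, `k`, `g` (diploid; reference copies) or `hap`
#'   (haploid; `"ref"`/`"alt"`), `gt` (VCF-style genotype string), and
#'   `GL0`, `GL1`, `GL2` (diploid log10 likelihoods).
#' @export
callGenotypes <- function(evidence, index, eps = 0.01,
                          ploidy = c("diploid", "haploid")) {
    ploidy <- match.arg(ploidy)
    panel <- if (methods::is(index, "PanelIndex")) index@panel else index
    counts <- evidence@counts
    sites <- panel@sites[panel@sites$marked, , drop = FALSE]
    if (nrow(counts) == 0L || nrow(sites) == 0L)
        return(.emptyCalls(ploidy))
    key <- paste(counts$chrom, counts$refOffset)
    skey <- paste(sites$chrom, sites$refOffset)
    known <- key %in% skey
    counts <- counts[known, , drop = FALSE]      # drop non-panel sites (QC)
    key <- key[known]
    out <- lapply(split(seq_len(nrow(counts)), key), function(ix) {
        cc <- counts[ix, , drop = FALSE]
        si <- sites[match(paste(cc$chrom[1L], cc$refOffset[1L]), skey), ]
        l <- sum(cc$count[cc$allele == 0L])
        k <- sum(cc$count)
        altCounts <- cc[cc$allele > 0L, , drop = FALSE]
        topAlt <- if (nrow(altCounts)) {
            altCounts$allele[which.max(altCounts$count)]
        } else 1L
        nAlt <- length(strsplit(si$alts, ",", fixed = TRUE)[[1L]])
        perAlt <- integer(nAlt)
        perAlt[altCounts$allele] <- altCounts$count
        ad <- paste(c(l, perAlt), collapse = ",")
        row <- data.frame(chrom = cc$chrom[1L],
                          chromName = panel@refNames[cc$chrom[1L] + 1L],
                          refOffset = cc$refOffset[1L],
                          ref = si$ref, alts = si$alts,
                          topAlt = as.integer(topAlt), l = l, k = k,
                          ad = ad)
        if (ploidy == "diploid") {
            cal <- callDiploid(l, k, eps)
            row$g <- cal$g
            row$gt <- c(paste0(topAlt, "/", topAlt),
                        paste0("0/", topAlt), "0/0")[cal$g + 1L]
            row$GL0 <- cal$GL[1L]; row$GL1 <- cal$GL[2L]; row$GL2 <- cal$GL[3L]
        } else {
            row$hap <- callHaploid(l, k)
            row$gt <- if (row$hap == "ref") "0" else as.character(topAlt)
        }
        row
    })
    out <- do.call(rbind, out)
    out <- out[order(out$chrom, out$refOffset), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyCalls <- function(ploidy) {
    base <- data.frame(chrom = integer(0), chromName = character(0),
                       refOffset = numeric(0), ref = character(0),
                       alts = character(0), topAlt = integer(0),
                       l = integer(0), k = integer(0), ad = character(0))
    if (ploidy == "diploid") {
        base$g <- integer(0); base$gt <- character(0)
        base$GL0 <- numeric(0); base$GL1 <- numeric(0); base$GL2 <- numeric(0)
    } else {
        base$hap <- character(0); base$gt <- character(0)
    }
    base
}
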