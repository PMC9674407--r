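## Evaluation: precision/recall of calls against a truth set.
##
## Haploid level: the positive class is marked sites that truly carry the
## alternate allele. Diploid ALT level: every diploid genotype splits into
## two allele calls; an ALT call is a true positive when the true genotype
## contains at least one ALT allele, a REF call is a true negative when it
## contains at least one REF allele, an ALT call against homozygous-REF
## truth is a false positive, and a REF call against homozygous-ALT truth a
## false negative. HET level: a heterozygous call at a truly heterozygous
## site is a true positive, with FP/FN/TN defined accordingly. Truth sites
## with no call contribute false negatives (one per true ALT allele at the
## ALT level; one per truly heterozygous site at the HET level); called
## sites absent from the truth cannot be assessed and are counted separately.

.prMetrics <- function(level, TP, FP, FN, TN) {
    data.frame(level = level, TP = TP, FP = FP, FN = FN, TN = TN,
               precision = TP / (TP + FP), recall = TP / (TP + FN))
}

#' Evaluate genotype calls against a truth set
#'
#' @param calls `data.frame` from [callGenotypes()] (diploid calls carry a
#'   `g` column of reference copies; haploid calls a `hap` column).
#' @param truth `data.frame` keyed by (`chrom`, `refOffset`); diploid truth
#'   carries allele columns `a1`, `a2` (0 = reference), haploid truth a
#'   single column `allele`.
#' @param includeMissing Count truth sites with no call as false negatives
#'   (default `TRUE`).
#' @return `data.frame` with one row per level (`"haploid"` or
#'   `"ALT"`/`"HET"`): TP, FP, FN, TN, precision and recall. Undefined
#'   ratios (zero denominators) are `NaN`. The number of calls that could
#'   not be assessed (sites absent from the truth) is attached as attribute
#'   `"unassessed"`.
#' @export
evaluateCalls <- function(calls, truth, includeMissing = TRUE) {
    ck <- paste(calls$chrom, calls$refOffset)
    tk <- paste(truth$chrom, truth$refOffset)
    shared <- ck %in% tk
    if (!any(shared) && nrow(calls) > 0L)
        warning("no overlap between called and truth sites; metrics reflect missed truth sites only")
    m <- match(ck[shared], tk)
    cc <- calls[shared, , drop = FALSE]
    missed <- if (includeMissing) truth[!(tk %in% ck), , drop = FALSE]
              else truth[0L, , drop = FALSE]

    if ("hap" %in% names(calls)) {
        truthAlt <- truth$allele[m] > 0L
        callAlt <- cc$hap == "alt"
        TP <- sum(callAlt & truthAlt)
        FP <- sum(callAlt & !truthAlt)
        FN <- sum(!callAlt & truthAlt) + sum(missed$allele > 0L)
        TN <- sum(!callAlt & !truthAlt)
        out <- .prMetrics("haploid", TP, FP, FN, TN)
    } else {
        gTruth <- (truth$a1[m] == 0L) + (truth$a2[m] == 0L)
        gCall <- cc$g
        hasAlt <- gTruth <= 1L
        hasRef <- gTruth >= 1L
        altCalls <- 2L - gCall
        refCalls <- gCall
        TPa <- sum(altCalls * hasAlt)
        FPa <- sum(altCalls * !hasAlt)
        TNa <- sum(refCalls * hasRef)
        FNa <- sum(refCalls * !hasRef)
        if (nrow(missed)) {
            gMiss <- (missed$a1 == 0L) + (missed$a2 == 0L)
            FNa <- FNa + sum(2L - gMiss)
        }
        hetCall <- gCall == 1L
        hetTruth <- gTruth == 1L
        TPh <- sum(hetCall & hetTruth)
        FPh <- sum(hetCall & !hetTruth)
        FNh <- sum(!hetCall & hetTruth)
        TNh <- sum(!hetCall & !hetTruth)
        if (nrow(missed)) {
            gMiss <- (missed$a1 == 0L) + (missed$a2 == 0L)
            FNh <- FNh + sum(gMiss == 1L)
        }
        out <- rbind(.prMetrics("ALT", TPa, FPa, FNa, TNa),
                     .prMetrics("HET", TPh, FPh, FNh, TNh))
    }
    attr(out, "unassessed") <- sum(!shared)
    out
}
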