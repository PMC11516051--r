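# Full-length classification against annotated translation start sites.

#' Classify reads as full-length
#'
#' A read is full-length when its 5' terminal aligned base reaches the
#' annotated translation start of its gene in transcription order: on `+`
#' genes `five_prime <= cds_start + slack`, on `-` genes
#' `five_prime >= cds_start - slack`. Reads assigned to genes without an
#' annotated CDS start, and unassigned reads, return `NA` and are excluded
#' from ratio denominators.
#'
#' @param reads GRanges from [assignReadsToGenes()].
#' @param geneModels A [GeneModels-class] object.
#' @param slack Tolerance in nt downstream of the start codon (default 0).
#' @return Logical vector parallel to `reads` (`NA` = not classifiable).
#' @export
classifyFullLength <- function(reads, geneModels, slack = 0L) {
    out <- rep(NA, length(reads))
    if (length(reads) == 0L) return(out)
    assigned <- which(reads$status == "Assigned")
    if (length(assigned) == 0L) return(out)
    cs <- cdsStart(geneModels)
    strands <- setNames(as.character(strand(geneRanges(geneModels))),
                        geneIds(geneModels))
    gid <- reads$gene_id[assigned]
    gcs <- cs[gid]
    gstr <- strands[gid]
    fp <- reads$five_prime[assigned]
    res <- ifelse(gstr == "+", fp <= gcs + slack, fp >= gcs - slack)
    res[is.na(gcs)] <- NA
    out[assigned] <- res
    out
}

#' Full-length ratio of a read set
#'
#' @param flags Logical vector from [classifyFullLength()]; `NA` entries
#'   (unclassifiable reads) are dropped from the denominator.
#' @return List with `n_full`, `n_total` and `ratio` (`NA` when no read is
#'   classifiable, with a warning).
#' @export
fullLengthRatio <- function(flags) {
    flags <- flags[!is.na(flags)]
    n_total <- length(flags)
    n_full <- sum(flags)
    if (n_total == 0L) {
        warning("no classifiable reads; full-length ratio undefined")
        return(list(n_full = 0L, n_total = 0L, ratio = NA_real_))
    }
    list(n_full = as.integer(n_full), n_total = as.integer(n_total),
         ratio = n_full / n_total)
}

#' Per-sample and per-condition full-length summaries
#'
#' Classifies every assigned read in every sample and reports per-sample
#' ratios plus condition-level summaries pooled over replicates
#' (`sum(n_full) / sum(n_total)`).
#'
#' @param readsBySample Named list of assigned-read GRanges per sample.
#' @param geneModels A [GeneModels-class] object.
#' @param sampleSheet data.frame with `sample_id` and `condition`.
#' @param slack Tolerance passed to [classifyFullLength()].
#' @return List of two data.frames, `perSample` (`sample_id`, `condition`,
#'   `n_full`, `n_total`, `ratio`) and `perCondition` (same without
#'   `sample_id`).
#' @export
fullLengthSummary <- function(readsBySample, geneModels, sampleSheet,
                              slack = 0L) {
    samples <- names(readsBySample)
    per <- do.call(rbind, lapply(samples, function(s) {
        fl <- fullLengthRatio(suppressWarnings(
            classifyFullLength(readsBySample[[s]], geneModels,
                               slack = slack)))
        data.frame(sample_id = s,
                   condition = sampleSheet$condition[
                       match(s, sampleSheet$sample_id)],
                   n_full = fl$n_full, n_total = fl$n_total,
                   ratio = fl$ratio, stringsAsFactors = FALSE)
    }))
    cond <- do.call(rbind, lapply(split(per, per$condition), function(d) {
        data.frame(condition = d$condition[1L],
                   n_full = sum(d$n_full), n_total = sum(d$n_total),
                   ratio = if (sum(d$n_total) > 0)
                       sum(d$n_full) / sum(d$n_total) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    rownames(cond) <- NULL
    list(perSample = per, perCondition = cond)
}

#' Compare full-length ratios between two conditions
#'
#' Reports the ratio difference and an auxiliary two-proportion z-test
#' p-value (pooled-variance, no continuity correction).
#'
#' @param nFullA,nTotalA,nFullB,nTotalB Full-length and total counts for
#'   the two conditions.
#' @return List with `ratio_a`, `ratio_b`, `difference` (a minus b), `z`
#'   and `p_value`.
#' @export
compareFullLength <- function(nFullA, nTotalA, nFullB, nTotalB) {
    stopifnot(nTotalA > 0, nTotalB > 0)
    pa <- nFullA / nTotalA
    pb <- nFullB / nTotalB
    pp <- (nFullA + nFullB) / (nTotalA + nTotalB)
    se <- sqrt(pp * (1 - pp) * (1 / nTotalA + 1 / nTotalB))
    z <- if (se == 0) 0 else (pa - pb) / se
    list(ratio_a = pa, ratio_b = pb, difference = pa - pb,
         z = z, p_value = 2 * pnorm(-abs(z)))
}
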