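# Polyadenylation-site clustering and APA calling with the RED score.
#
# A read's PAS is the genomic coordinate of its 3' terminal aligned base.
# Sites within 24 nt of each other (single-linkage chaining over sorted
# positions) form one cluster; a cluster's reporting site is its most
# abundant member position; clusters need >= 3 supporting reads overall to
# be retained. APA on the most-3' exon contrasts the two most abundant
# clusters via the relative expression difference (RED):
# RED_c = log2(distal_c / proximal_c), delta RED = |RED_1 - RED_2|.

#' Per-read polyadenylation site
#'
#' The PAS of a read is the genomic coordinate of its 3' terminal aligned
#' base: the alignment end on `+`, the alignment start on `-`.
#'
#' @param reads GRanges from [loadAlignments()].
#' @return Integer vector of genomic PAS coordinates (1-based).
#' @export
extractReadPas <- function(reads) {
    as.integer(reads$three_prime)
}

#' Single-linkage PAS clustering
#'
#' Chains sorted unique positions: a new cluster starts whenever the gap to
#' the previous position exceeds `maxGap`. The clusters partition the input
#' and are ordered by coordinate. Positions exactly `maxGap` apart fall in
#' the same cluster ("within `maxGap` nt").
#'
#' @param positions Integer vector (multiset) of PAS coordinates from one
#'   gene and strand.
#' @param maxGap Maximum gap between neighbouring member positions
#'   (default 24 nt).
#' @return data.frame with columns `position`, `count`, `cluster` (1-based
#'   cluster index in coordinate order); zero rows for empty input.
#' @export
clusterPas <- function(positions, maxGap = 24L) {
    if (length(positions) == 0L)
        return(data.frame(position = integer(), count = integer(),
                          cluster = integer()))
    tab <- table(positions)
    pos <- as.integer(names(tab))
    o <- order(pos)
    pos <- pos[o]
    cnt <- as.integer(tab)[o]
    cl <- cumsum(c(1L, as.integer(diff(pos) > maxGap)))
    data.frame(position = pos, count = cnt, cluster = cl)
}

#' Representative site of a PAS cluster
#'
#' The reporting site is the member position with the highest read count;
#' ties are broken toward the most-3' position in transcription order (the
#' higher coordinate on `+`, the lower on `-`). A cluster is retained only
#' when its total support reaches `minSupport` reads.
#'
#' @param positions,counts Parallel vectors of member positions and their
#'   read counts.
#' @param strand `"+"` or `"-"`.
#' @param minSupport Minimum total supporting reads (default 3).
#' @return List with `representative`, `support` and `retained`.
#' @export
selectRepresentative <- function(positions, counts, strand,
                                 minSupport = 3L) {
    stopifnot(length(positions) == length(counts), length(positions) > 0L)
    best <- which(counts == max(counts))
    rep_pos <- if (strand == "+") max(positions[best])
               else min(positions[best])
    support <- sum(counts)
    list(representative = as.integer(rep_pos),
         support = as.integer(support),
         retained = support >= minSupport)
}

#' RPM normalisation
#'
#' Reads-per-million scaling of per-cluster counts against each sample's
#' total assigned read count.
#'
#' @param counts Numeric matrix (clusters x samples) or vector.
#' @param totals Per-sample totals of assigned reads, recycled across rows.
#' @return Matrix (or vector) of RPM values.
#' @export
rpmNormalize <- function(counts, totals) {
    if (any(totals <= 0))
        stop("RPM normalisation requires positive library totals")
    if (is.matrix(counts)) {
        if (length(totals) != ncol(counts))
            stop("length(totals) must equal ncol(counts)")
        sweep(counts, 2L, totals, "/") * 1e6
    } else {
        counts / totals * 1e6
    }
}

#' Build the PAS cluster experiment
#'
#' Pools per-read PAS positions across all samples for each gene, clusters
#' them by single-linkage chaining ([clusterPas()]), selects each cluster's
#' representative site and drops clusters with fewer than `minSupport`
#' supporting reads in total ([selectRepresentative()]). Returns a
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are retained
#' clusters (span plus `gene_id`, `representative`, `support`,
#' `on_most3p_exon`), columns are samples, with `counts` and `rpm` assays.
#' RPM uses each sample's total contributing (assigned, QC-PASS) read count
#' as the denominator.
#'
#' @param readsBySample Named list of assigned-read GRanges, one per sample,
#'   already restricted to the reads eligible for PAS analysis (status
#'   `Assigned`, poly(A) QC PASS).
#' @param geneModels A [GeneModels-class] object.
#' @param sampleSheet data.frame with `sample_id` and `condition` columns
#'   covering `names(readsBySample)`.
#' @param maxGap Clustering gap (default 24 nt).
#' @param minSupport Minimum total reads per retained cluster (default 3).
#' @return A RangedSummarizedExperiment of retained PAS clusters.
#' @export
pasClusterExperiment <- function(readsBySample, geneModels, sampleSheet,
                                 maxGap = 24L, minSupport = 3L) {
    samples <- names(readsBySample)
    stopifnot(!is.null(samples), all(samples %in% sampleSheet$sample_id))
    sheet <- sampleSheet[match(samples, sampleSheet$sample_id), ,
                         drop = FALSE]

    pas <- do.call(rbind, lapply(samples, function(s) {
        r <- readsBySample[[s]]
        keep <- r$status == "Assigned"
        data.frame(sample = rep(s, sum(keep)),
                   gene_id = r$gene_id[keep],
                   pas = extractReadPas(r[keep]),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(pas))
        pas <- data.frame(sample = character(), gene_id = character(),
                          pas = integer(), stringsAsFactors = FALSE)
    totals <- vapply(samples, function(s)
        sum(pas$sample == s), numeric(1))

    gm_idx <- match(unique(pas$gene_id), geneIds(geneModels))
    gm <- geneModels[gm_idx[!is.na(gm_idx)]]
    m3e <- most3pExon(gm)
    g <- geneRanges(gm)
    gstr <- setNames(as.character(strand(g)), g$gene_id)
    gchrom <- setNames(as.character(seqnames(g)), g$gene_id)
    m3e_start <- setNames(start(m3e), names(m3e))
    m3e_end <- setNames(end(m3e), names(m3e))

    sample_i <- match(pas$sample, samples)
    pas_by_gene <- split(seq_len(nrow(pas)), pas$gene_id)

    rows <- list(); cmat <- list()
    for (gid in g$gene_id) {
        idx <- pas_by_gene[[gid]]
        if (is.null(idx)) next
        positions <- pas$pas[idx]
        cl <- clusterPas(positions, maxGap = maxGap)
        if (nrow(cl) == 0L) next
        str <- gstr[[gid]]
        read_cl <- cl$cluster[match(positions, cl$position)]
        nK <- max(cl$cluster)
        # per-cluster, per-sample read counts in one pass
        tab <- matrix(tabulate((sample_i[idx] - 1L) * nK + read_cl,
                               nbins = nK * length(samples)),
                      nrow = nK, ncol = length(samples))
        for (k in seq_len(nK)) {
            mem <- cl[cl$cluster == k, , drop = FALSE]
            rep <- selectRepresentative(mem$position, mem$count, str,
                                        minSupport = minSupport)
            if (!rep$retained) next
            on3p <- rep$representative >= m3e_start[[gid]] &
                    rep$representative <= m3e_end[[gid]]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = gchrom[[gid]],
                start = min(mem$position), end = max(mem$position),
                strand = str, gene_id = gid,
                representative = rep$representative,
                support = rep$support, on_most3p_exon = on3p,
                stringsAsFactors = FALSE)
            cmat[[length(cmat) + 1L]] <- tab[k, ]
        }
    }
    if (length(rows) == 0L) {
        rr <- GRanges()
        counts <- matrix(0, nrow = 0L, ncol = length(samples),
                         dimnames = list(NULL, samples))
    } else {
        tab <- do.call(rbind, rows)
        rr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), tab$strand,
                      gene_id = tab$gene_id,
                      representative = tab$representative,
                      support = tab$support,
                      on_most3p_exon = tab$on_most3p_exon)
        names(rr) <- paste0(tab$gene_id, ":c",
                            ave(seq_len(nrow(tab)), tab$gene_id,
                                FUN = seq_along))
        counts <- do.call(rbind, cmat)
        dimnames(counts) <- list(names(rr), samples)
    }
    cd <- DataFrame(sheet, total_assigned = as.numeric(totals),
                    row.names = samples)
    rpm <- if (nrow(counts) && all(totals > 0))
        rpmNormalize(counts, totals) else counts
    SummarizedExperiment(assays = list(counts = counts, rpm = rpm),
                         rowRanges = rr, colData = cd)
}

#' Export PAS clusters as BED6
#'
#' One line per retained cluster: the cluster span (0-based half-open), the
#' name `gene:cluster`, the pooled support as score, and the strand.
#'
#' @param se RangedSummarizedExperiment from [pasClusterExperiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportClustersBed <- function(se, path) {
    rr <- rowRanges(se)
    bed <- data.frame(chrom = as.character(seqnames(rr)),
                      start = start(rr) - 1L,
                      end = end(rr),
                      name = names(rr),
                      score = rr$support,
                      strand = as.character(strand(rr)),
                      stringsAsFactors = FALSE)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Relative expression difference between conditions
#'
#' `deltaRed(p1, d1, p2, d2)` is `|log2(d1/p1) - log2(d2/p2)|`, the absolute
#' between-condition difference of the per-condition distal/proximal log2
#' ratios. Algebraically identical to `|log2(d1/d2) - log2(p1/p2)|`.
#'
#' @param p1,d1 Proximal and distal abundances in condition 1.
#' @param p2,d2 Proximal and distal abundances in condition 2.
#' @return Non-negative numeric vector.
#' @export
deltaRed <- function(p1, d1, p2, d2) {
    abs(log2(d1 / p1) - log2(d2 / p2))
}

#' Call alternative polyadenylation on the most-3' exon
#'
#' For each gene with at least two retained clusters whose representative
#' site lies on the most-3' exon, the two clusters with the highest pooled
#' abundance (RPM summed over the two conditions) are contrasted. The
#' cluster nearer the translation stop in transcription order is the
#' proximal PAS (pPAS), the farther the distal (dPAS). Per condition,
#' `RED_c = log2(dPAS_c / pPAS_c)` on condition-level RPM (replicate counts
#' pooled, normalised by the condition's total assigned reads); the gene is
#' significant when `deltaRed = |RED_1 - RED_2|` exceeds `redThreshold`.
#' The 3' UTR is shorter in the condition with the smaller RED.
#'
#' Genes are reported not-testable (with a `status` reason) when fewer than
#' two on-most-3'-exon clusters exist, when the candidate pair lacks
#' `minSupportCondition` reads in each condition, or when any of the four
#' abundances is zero; no pseudocount is applied.
#'
#' @param se RangedSummarizedExperiment from [pasClusterExperiment()].
#' @param geneModels A [GeneModels-class] object.
#' @param conditions The two condition labels, in the order defining
#'   `red_1` and `red_2`.
#' @param redThreshold Significance cutoff on `delta_red`; default
#'   `log2(1.3)`, the log2 mapping of a 30% change in relative abundance.
#' @param minSupportCondition Minimum reads per cluster per condition for
#'   the pair to be testable (default 3).
#' @return data.frame with one row per gene that has any retained cluster
#'   on its most-3' exon: `gene_id`, `status` (`testable` or a reason),
#'   `pPAS`, `dPAS` (representative coordinates), per-condition counts and
#'   RPM, `red_1`, `red_2`, `delta_red`, `significant`, `direction`.
#' @export
callApa <- function(se, geneModels, conditions,
                    redThreshold = log2(1.3), minSupportCondition = 3L) {
    stopifnot(length(conditions) == 2L)
    empty <- data.frame(gene_id = character(), status = character(),
                        pPAS = integer(), dPAS = integer(),
                        p_count_1 = numeric(), d_count_1 = numeric(),
                        p_count_2 = numeric(), d_count_2 = numeric(),
                        p_rpm_1 = numeric(), d_rpm_1 = numeric(),
                        p_rpm_2 = numeric(), d_rpm_2 = numeric(),
                        red_1 = numeric(), red_2 = numeric(),
                        delta_red = numeric(), significant = logical(),
                        direction = character(), stringsAsFactors = FALSE)
    if (nrow(se) == 0L) return(empty)
    cd <- colData(se)
    if (!all(conditions %in% cd$condition))
        stop("conditions not found in the experiment: ",
             paste(setdiff(conditions, cd$condition), collapse = ", "))
    counts <- assay(se, "counts")
    cond_counts <- vapply(conditions, function(cc)
        rowSums(counts[, cd$condition == cc, drop = FALSE]),
        numeric(nrow(se)))
    cond_totals <- vapply(conditions, function(cc)
        sum(cd$total_assigned[cd$condition == cc]), numeric(1))
    if (nrow(se) > 0L && any(cond_totals <= 0))
        stop("a condition has zero assigned reads; cannot normalise")
    cond_rpm <- if (nrow(se)) rpmNormalize(cond_counts, cond_totals)
                else cond_counts

    rr <- rowRanges(se)
    on3p <- which(rr$on_most3p_exon)
    genes <- unique(rr$gene_id[on3p])
    if (length(genes) == 0L) return(empty)

    rows <- lapply(genes, function(gid) {
        idx <- on3p[rr$gene_id[on3p] == gid]
        out <- data.frame(gene_id = gid, status = "testable",
                          pPAS = NA_integer_, dPAS = NA_integer_,
                          p_count_1 = NA_real_, d_count_1 = NA_real_,
                          p_count_2 = NA_real_, d_count_2 = NA_real_,
                          p_rpm_1 = NA_real_, d_rpm_1 = NA_real_,
                          p_rpm_2 = NA_real_, d_rpm_2 = NA_real_,
                          red_1 = NA_real_, red_2 = NA_real_,
                          delta_red = NA_real_, significant = NA,
                          direction = NA_character_,
                          stringsAsFactors = FALSE)
        if (length(idx) < 2L) {
            out$status <- "lt2_clusters"; return(out)
        }
        eligible <- idx[cond_counts[idx, 1L] >= minSupportCondition &
                        cond_counts[idx, 2L] >= minSupportCondition]
        if (length(eligible) < 2L) {
            out$status <- "insufficient_support"; return(out)
        }
        pooled <- cond_rpm[eligible, 1L] + cond_rpm[eligible, 2L]
        ord <- eligible[order(-pooled, rr$representative[eligible])]
        pair <- ord[1:2]
        str <- as.character(strand(rr[pair[1L]]))
        # proximal = nearer the stop codon in transcription order
        prox_first <- if (str == "+")
            rr$representative[pair[1L]] < rr$representative[pair[2L]]
        else rr$representative[pair[1L]] > rr$representative[pair[2L]]
        p_i <- pair[if (prox_first) 1L else 2L]
        d_i <- pair[if (prox_first) 2L else 1L]
        ab <- c(cond_rpm[p_i, 1L], cond_rpm[d_i, 1L],
                cond_rpm[p_i, 2L], cond_rpm[d_i, 2L])
        out$pPAS <- rr$representative[p_i]
        out$dPAS <- rr$representative[d_i]
        out$p_count_1 <- cond_counts[p_i, 1L]
        out$d_count_1 <- cond_counts[d_i, 1L]
        out$p_count_2 <- cond_counts[p_i, 2L]
        out$d_count_2 <- cond_counts[d_i, 2L]
        out$p_rpm_1 <- ab[1L]; out$d_rpm_1 <- ab[2L]
        out$p_rpm_2 <- ab[3L]; out$d_rpm_2 <- ab[4L]
        if (any(ab == 0)) {
            out$status <- "zero_abundance"; return(out)
        }
        out$red_1 <- log2(ab[2L] / ab[1L])
        out$red_2 <- log2(ab[4L] / ab[3L])
        out$delta_red <- abs(out$red_1 - out$red_2)
        out$significant <- out$delta_red > redThreshold
        out$direction <- if (out$red_1 == out$red_2) "none"
            else paste0("shorter_in_",
                        conditions[if (out$red_1 < out$red_2) 1L else 2L])
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
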