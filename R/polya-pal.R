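# Per-read poly(A) calls, per-gene PAL summaries and differential PAL.

#' Read a nanopolish-style poly(A) table
#'
#' Loads the tab-separated per-read poly(A) report dialect produced by the
#' nanopolish `polya` subcommand. The columns `readname` (or `read_id`),
#' `polya_length` and `qc_tag` are required; others are ignored. Only
#' records with `qc_tag == "PASS"` are retained by default. Duplicate read
#' names are resolved by keeping the first occurrence, with a warning.
#'
#' @param path File path.
#' @param passOnly Keep only QC-PASS records (default `TRUE`).
#' @return A data.frame with columns `read_id`, `polya_length`, `qc_tag`.
#'   Attributes `n_total` and `n_pass` record the de-duplicated record count
#'   and the PASS count, for filter auditing.
#' @export
readPolyATable <- function(path, passOnly = TRUE) {
    if (!file.exists(path)) stop("poly(A) table not found: ", path)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if ("readname" %in% colnames(tab) && !"read_id" %in% colnames(tab))
        colnames(tab)[colnames(tab) == "readname"] <- "read_id"
    req <- c("read_id", "polya_length", "qc_tag")
    missing_cols <- setdiff(req, colnames(tab))
    if (length(missing_cols))
        stop("poly(A) table ", path, " is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    dup <- duplicated(tab$read_id)
    if (any(dup)) {
        warning(sum(dup), " duplicated read name(s) in ", path,
                "; keeping first occurrence")
        tab <- tab[!dup, , drop = FALSE]
    }
    out <- tab[, req]
    n_total <- nrow(out)
    n_pass <- sum(out$qc_tag == "PASS")
    if (passOnly) out <- out[out$qc_tag == "PASS", , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_total") <- n_total
    attr(out, "n_pass") <- n_pass
    out
}

#' Per-gene poly(A) length vectors
#'
#' Joins assigned reads with QC-PASS poly(A) calls and splits the tail
#' lengths by gene. Only reads that are both `Assigned` and present in the
#' poly(A) table participate.
#'
#' @param reads GRanges from [assignReadsToGenes()].
#' @param polya data.frame from [readPolyATable()].
#' @return Named list mapping gene_id to a numeric vector of per-read
#'   poly(A) lengths.
#' @export
palByGene <- function(reads, polya) {
    keep <- reads$status == "Assigned"
    ids <- reads$read_id[keep]
    genes <- reads$gene_id[keep]
    m <- match(ids, polya$read_id)
    ok <- !is.na(m)
    split(polya$polya_length[m[ok]], genes[ok])
}

#' Per-gene median PAL summary
#'
#' The per-gene PAL is the median tail length over all contributing reads
#' (standard order statistic; mean of the central pair for even counts).
#' Genes with fewer than `minReads` reads get an `NA` median but keep their
#' read count.
#'
#' @param pals Named list from [palByGene()].
#' @param minReads Minimum reads for a defined median (default 1).
#' @return data.frame with columns `gene_id`, `n`, `median_pal`.
#' @export
genePal <- function(pals, minReads = 1L) {
    n <- lengths(pals)
    med <- vapply(pals, median, numeric(1))
    med[n < minReads] <- NA_real_
    data.frame(gene_id = names(pals), n = as.integer(n), median_pal = med,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential poly(A) tail length between two conditions
#'
#' For every gene with at least `minReads` reads in both conditions (reads
#' pooled across replicates within a condition), compares the read-level PAL
#' samples with a two-sided Wilcoxon rank-sum test and computes the fold
#' change of condition medians, oriented as max/min with a direction flag
#' naming the condition with the longer median. A gene is significant when
#' `p < alpha` and fold change strictly exceeds `fcThreshold`. Genes where
#' one condition median is zero and the other is not get an infinite fold
#' change and are flagged `zero_median` for manual review instead of being
#' auto-called. A Benjamini-Hochberg adjusted p-value column is provided for
#' convenience; the significance rule uses the raw p-value.
#'
#' @param palsA,palsB Named lists (gene_id -> numeric PAL vector) for the
#'   two conditions, as from [palByGene()] on pooled condition reads.
#' @param conditions Character vector of the two condition labels, parallel
#'   to (`palsA`, `palsB`); used for the direction flag.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param fcThreshold Fold-change cutoff, strict (default 1.5).
#' @param minReads Minimum reads per condition for a gene to be tested
#'   (default 10); genes failing it are excluded, not reported.
#' @param exact Passed to [stats::wilcox.test()]; default `FALSE` (normal
#'   approximation with continuity correction).
#' @return data.frame with columns `gene_id`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `fold_change`, `direction`, `p_value`, `padj`,
#'   `significant`, `flag`.
#' @export
differentialPal <- function(palsA, palsB, conditions = c("A", "B"),
                            alpha = 0.05, fcThreshold = 1.5,
                            minReads = 10L, exact = FALSE) {
    stopifnot(length(conditions) == 2L)
    genes <- intersect(names(palsA), names(palsB))
    genes <- genes[lengths(palsA[genes]) >= minReads &
                   lengths(palsB[genes]) >= minReads]
    if (length(genes) == 0L)
        return(data.frame(gene_id = character(), n_a = integer(),
                          n_b = integer(), median_a = numeric(),
                          median_b = numeric(), fold_change = numeric(),
                          direction = character(), p_value = numeric(),
                          padj = numeric(), significant = logical(),
                          flag = character(), stringsAsFactors = FALSE))
    res <- lapply(genes, function(g) {
        a <- palsA[[g]]; b <- palsB[[g]]
        ma <- median(a); mb <- median(b)
        if (ma == 0 && mb == 0) {
            fc <- 1; dir <- "none"; flag <- "zero_median"
        } else if (ma == 0 || mb == 0) {
            fc <- Inf
            dir <- conditions[if (ma > mb) 1L else 2L]
            flag <- "zero_median"
        } else {
            fc <- max(ma, mb) / min(ma, mb)
            dir <- if (ma == mb) "none"
                   else conditions[if (ma > mb) 1L else 2L]
            flag <- ""
        }
        p <- suppressWarnings(
            wilcox.test(a, b, alternative = "two.sided",
                        exact = exact)$p.value)
        c(n_a = length(a), n_b = length(b), median_a = ma, median_b = mb,
          fold_change = fc, p_value = p,
          dir_idx = match(dir, c(conditions, "none")),
          flagged = as.integer(nzchar(flag)))
    })
    res <- do.call(rbind, res)
    dirs <- c(conditions, "none")[res[, "dir_idx"]]
    flags <- ifelse(res[, "flagged"] == 1L, "zero_median", "")
    out <- data.frame(
        gene_id = genes,
        n_a = as.integer(res[, "n_a"]),
        n_b = as.integer(res[, "n_b"]),
        median_a = res[, "median_a"],
        median_b = res[, "median_b"],
        fold_change = res[, "fold_change"],
        direction = dirs,
        p_value = res[, "p_value"],
        padj = p.adjust(res[, "p_value"], method = "BH"),
        significant = res[, "p_value"] < alpha &
            res[, "fold_change"] > fcThreshold &
            is.finite(res[, "fold_change"]),
        flag = flags,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
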