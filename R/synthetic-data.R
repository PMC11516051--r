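# Ground-truthed synthetic DRS data: annotation, alignments, poly(A) tables.
#
# The default scenario emulates the two-tissue design the pipeline targets:
# an undifferentiated "callus"-like condition with higher 5'-completeness,
# longer poly(A) tails in a designated gene subset, and higher proximal-PAS
# usage (shorter 3' UTRs) in a designated APA subset, versus a
# differentiated "xylem"-like condition; two replicates per condition.

#' Configuration for the synthetic DRS scenario
#'
#' All knobs of the generator with defaults describing the default
#' two-condition scenario. Genes are laid out round-robin across
#' chromosomes, strands alternating, each with three exons (the last in
#' transcription order carrying two ground-truth PAS positions) and a CDS
#' start inside the first exon.
#'
#' @param nGenes Number of genes (default 200).
#' @param nChroms Number of chromosomes (default 4).
#' @param geneSpacing Intergenic gap in nt (default 2000).
#' @param exonLengths Exon lengths in transcription order; the last exon is
#'   the most-3' exon and must accommodate both PAS sites (default
#'   `c(600, 400, 1200)`).
#' @param intronLength Intron length between consecutive exons (default 300).
#' @param cdsOffset Offset of the start codon into the first exon (default
#'   150 nt).
#' @param conditions The two condition labels (default callus, xylem).
#' @param replicates Replicates per condition (default 2).
#' @param readsPerGene Reads per gene per sample (default 50).
#' @param completeness Named per-condition probability that a read's 5' end
#'   reaches the translation start (default callus 0.8, xylem 0.6).
#' @param palGrandMedian Grand median of per-gene baseline PAL in nt
#'   (default 100); gene baselines are log-normal around it
#'   (`palBetweenGeneSdlog`).
#' @param palBetweenGeneSdlog Between-gene spread of baseline medians on the
#'   log scale (default 0.25).
#' @param palSdlog Within-gene read-level log-normal spread (default 0.20).
#' @param palDiffFraction Fraction of genes with a condition PAL shift
#'   (default 0.15).
#' @param palFoldChange Median fold change injected in shifted genes
#'   (default 2).
#' @param palLongerIn Condition with the longer tails in shifted genes
#'   (default the first condition).
#' @param pasEndOffset Distance of the distal PAS from the annotated 3' end
#'   (default 40 nt).
#' @param pasSeparation Distance between proximal and distal PAS (default
#'   120 nt; must exceed `24 + 2 * jitterMax` so truth sites cannot chain
#'   into one cluster).
#' @param apaShiftFraction Fraction of genes with an APA usage shift
#'   (default 0.15).
#' @param apaDeltaRed Injected between-condition RED difference in shifted
#'   genes (default 2).
#' @param apaShorterIn Condition with the shorter 3' UTR (higher proximal
#'   usage) in shifted genes (default the first condition).
#' @param jitterSd,jitterMax 3'-end positional jitter: rounded normal with
#'   this SD, truncated at `±jitterMax` (defaults 3 and 10 nt).
#' @param qcFailProb Probability a read's poly(A) call fails QC (default
#'   0.05).
#' @param chromLength Optional fixed chromosome length; the layout must fit
#'   or generation aborts with a sizing hint. `NULL` (default) sizes
#'   chromosomes to the content.
#' @param seed Random seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 200L,
                            nChroms = 4L,
                            geneSpacing = 2000L,
                            exonLengths = c(600L, 400L, 1200L),
                            intronLength = 300L,
                            cdsOffset = 150L,
                            conditions = c("callus", "xylem"),
                            replicates = 2L,
                            readsPerGene = 50L,
                            completeness = c(callus = 0.8, xylem = 0.6),
                            palGrandMedian = 100,
                            palBetweenGeneSdlog = 0.25,
                            palSdlog = 0.20,
                            palDiffFraction = 0.15,
                            palFoldChange = 2,
                            palLongerIn = conditions[1L],
                            pasEndOffset = 40L,
                            pasSeparation = 120L,
                            apaShiftFraction = 0.15,
                            apaDeltaRed = 2,
                            apaShorterIn = conditions[1L],
                            jitterSd = 3,
                            jitterMax = 10L,
                            qcFailProb = 0.05,
                            chromLength = NULL,
                            seed = 42L) {
    cfg <- as.list(environment())
    stopifnot(length(conditions) == 2L, !anyDuplicated(conditions),
              nGenes >= 1L, nChroms >= 1L, replicates >= 1L,
              readsPerGene >= 1L, length(exonLengths) >= 2L,
              cdsOffset < exonLengths[1L])
    if (is.null(names(completeness)))
        names(cfg$completeness) <- conditions
    if (!all(conditions %in% names(cfg$completeness)))
        stop("completeness must be named by condition")
    probs <- c(cfg$completeness, palDiffFraction, apaShiftFraction,
               qcFailProb)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    if (pasSeparation <= 24L)
        stop("pasSeparation must exceed the 24 nt clustering gap")
    if (pasSeparation <= 24L + 2L * jitterMax)
        warning("pasSeparation <= 24 + 2*jitterMax: jittered truth sites ",
                "may chain into one cluster")
    e3 <- exonLengths[length(exonLengths)]
    if (pasEndOffset + pasSeparation + jitterMax >= e3)
        stop("most-3' exon too short for the two PAS sites; increase the ",
             "last exon length or reduce pasSeparation/pasEndOffset")
    if (!palLongerIn %in% conditions || !apaShorterIn %in% conditions)
        stop("palLongerIn and apaShorterIn must be one of the conditions")
    structure(cfg, class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
    cat(sprintf(
        "SyntheticConfig: %d genes x %d reads/gene/sample; %s vs %s (%d reps)\n",
        x$nGenes, x$readsPerGene, x$conditions[1L], x$conditions[2L],
        x$replicates))
    cat(sprintf("  completeness: %s; PAL fc %.2g in %d%% of genes; dRED %.2g in %d%%\n",
                paste(sprintf("%s=%.2f", names(x$completeness),
                              x$completeness), collapse = ", "),
                x$palFoldChange, round(100 * x$palDiffFraction),
                x$apaDeltaRed, round(100 * x$apaShiftFraction)))
    invisible(x)
}

# deterministic genomic layout of gene i (1-based start coordinate)
.geneLayout <- function(config) {
    E <- config$exonLengths
    L <- sum(E) + (length(E) - 1L) * config$intronLength
    chrom_idx <- ((seq_len(config$nGenes) - 1L) %% config$nChroms) + 1L
    slot <- (seq_len(config$nGenes) - 1L) %/% config$nChroms
    starts <- 1L + slot * (L + config$geneSpacing)
    strands <- rep(c("+", "-"), length.out = config$nGenes)
    need <- max(starts + L - 1L) + config$geneSpacing
    if (!is.null(config$chromLength) && need > config$chromLength)
        stop("gene layout exceeds chromLength (needs ", need,
             " nt); increase chromLength or reduce nGenes/geneSpacing")
    list(chrom = paste0("chr", chrom_idx), start = starts,
         strand = strands, gene_length = L,
         chrom_length = if (is.null(config$chromLength)) need
                        else config$chromLength)
}

#' Generate the synthetic annotation and gene-level truth
#'
#' Lays out `nGenes` multi-exon genes on both strands, assigns each a CDS
#' start inside the first exon (transcription order) and two ground-truth
#' PAS positions on the most-3' exon, and draws the latent per-gene,
#' per-condition PAL medians and PAS usage proportions, including the
#' designated differential-PAL and APA-shift subsets.
#'
#' @param config A [syntheticConfig()] object.
#' @param dir Optional output directory; when given, writes
#'   `annotation.gff3` and `truth_genes.tsv`.
#' @return List with `models` ([GeneModels-class]), `truth` (gene-level
#'   truth data.frame) and, when `dir` is given, the file `paths`.
#' @export
generateAnnotation <- function(config, dir = NULL) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed)
    lay <- .geneLayout(config)
    E <- config$exonLengths
    nE <- length(E)
    I <- config$intronLength
    n <- config$nGenes
    gene_id <- sprintf("g%04d", seq_len(n))
    ends <- lay$start + lay$gene_length - 1L

    exon_list <- vector("list", n)
    cds_start <- integer(n)
    prox <- integer(n); dist <- integer(n)
    for (i in seq_len(n)) {
        s <- lay$start[i]; e <- ends[i]
        if (lay$strand[i] == "+") {
            widths <- E
        } else {
            widths <- rev(E)   # most-3' exon is the lowest-coordinate one
        }
        exs <- integer(0); cur <- s
        for (w in widths) {
            exs <- c(exs, cur, cur + w - 1L)
            cur <- cur + w + I
        }
        st <- exs[seq(1L, length(exs), 2L)]
        en <- exs[seq(2L, length(exs), 2L)]
        exon_list[[i]] <- GRanges(lay$chrom[i], IRanges(st, en),
                                  lay$strand[i])
        if (lay$strand[i] == "+") {
            cds_start[i] <- s + config$cdsOffset
            dist[i] <- e - config$pasEndOffset
            prox[i] <- dist[i] - config$pasSeparation
        } else {
            cds_start[i] <- e - config$cdsOffset
            dist[i] <- s + config$pasEndOffset
            prox[i] <- dist[i] + config$pasSeparation
        }
    }
    g <- GRanges(lay$chrom, IRanges(lay$start, ends), lay$strand,
                 gene_id = gene_id, tx_id = paste0(gene_id, ".t1"),
                 cds_start = cds_start)
    sl <- setNames(rep(lay$chrom_length, config$nChroms),
                   paste0("chr", seq_len(config$nChroms)))
    seqlevels(g) <- names(sl)
    seqlengths(g) <- sl
    ex <- GRangesList(lapply(exon_list, function(x) {
        seqlevels(x) <- names(sl); seqlengths(x) <- sl; x
    }))
    names(ex) <- gene_id
    models <- GeneModels(g, ex)

    # latent per-gene truth
    conds <- config$conditions
    base_med <- rlnorm(n, log(config$palGrandMedian),
                       config$palBetweenGeneSdlog)
    pal_diff <- logical(n)
    pal_diff[sample.int(n, round(config$palDiffFraction * n))] <- TRUE
    apa_shift <- logical(n)
    apa_shift[sample.int(n, round(config$apaShiftFraction * n))] <- TRUE

    pal_med <- matrix(base_med, n, 2L, dimnames = list(gene_id, conds))
    longer <- match(config$palLongerIn, conds)
    pal_med[pal_diff, longer] <- base_med[pal_diff] * config$palFoldChange

    usage_prox <- matrix(0.5, n, 2L, dimnames = list(gene_id, conds))
    shorter <- match(config$apaShorterIn, conds)
    p_shift <- 2^config$apaDeltaRed / (2^config$apaDeltaRed + 1)
    usage_prox[apa_shift, shorter] <- p_shift
    dr_true <- abs(log2((1 - usage_prox[, 1L]) / usage_prox[, 1L]) -
                   log2((1 - usage_prox[, 2L]) / usage_prox[, 2L]))

    truth <- data.frame(
        gene_id = gene_id, chrom = lay$chrom, strand = lay$strand,
        start = lay$start, end = ends, cds_start = cds_start,
        proximal_pas = prox, distal_pas = dist,
        pal_diff = pal_diff, apa_shift = apa_shift,
        delta_red_true = dr_true, stringsAsFactors = FALSE)
    truth[[paste0("pal_median_", conds[1L])]] <- pal_med[, 1L]
    truth[[paste0("pal_median_", conds[2L])]] <- pal_med[, 2L]
    truth[[paste0("usage_proximal_", conds[1L])]] <- usage_prox[, 1L]
    truth[[paste0("usage_proximal_", conds[2L])]] <- usage_prox[, 2L]

    out <- list(models = models, truth = truth)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        gff <- file.path(dir, "annotation.gff3")
        tg <- file.path(dir, "truth_genes.tsv")
        writeGeneModels(models, gff)
        .writeTsv(truth, tg)
        out$paths <- c(annotation = gff, truth_genes = tg)
    }
    out
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Simulate reads for every sample of the scenario
#'
#' For each sample (condition x replicate) and gene, draws `readsPerGene`
#' reads: the 3' end is one of the gene's two truth PAS positions (chosen
#' from the condition's usage mixture) plus bounded integer jitter; the 5'
#' end reaches the translation start with the condition's completeness
#' probability and is otherwise truncated uniformly inside the gene body;
#' the poly(A) length is log-normal around the gene/condition median; the
#' QC tag fails with probability `qcFailProb`. Every latent choice is
#' recorded in the read-level truth table.
#'
#' @param config A [syntheticConfig()] object.
#' @param annotation Result of [generateAnnotation()].
#' @param dir Output directory (created if needed).
#' @param emitBam Also write a coordinate-sorted, indexed BAM per sample
#'   (default `FALSE`; the TSV alignment dialect is always written).
#' @return List with `sampleSheet` (data.frame), `truthReads` (data.frame)
#'   and `paths` (named vector: sample sheet, truth table, per-sample
#'   files).
#' @export
simulateReads <- function(config, annotation, dir, emitBam = FALSE) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed + 1000003L)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    truth <- annotation$truth
    models <- annotation$models
    conds <- config$conditions
    n <- config$nGenes
    rpg <- config$readsPerGene
    N <- n * rpg

    gidx <- rep(seq_len(n), each = rpg)
    plus <- truth$strand[gidx] == "+"
    cds <- truth$cds_start[gidx]
    upmax <- pmin(100L, config$cdsOffset)

    sheet <- expand.grid(replicate = seq_len(config$replicates),
                         condition = conds, stringsAsFactors = FALSE)
    sheet <- sheet[order(match(sheet$condition, conds), sheet$replicate), ]
    sheet$sample_id <- paste0(sheet$condition, "_rep", sheet$replicate)

    truth_reads <- list()
    paths <- c()
    qc_fail_tags <- c("ADAPTER", "SUFFCLIP", "NOREGION")

    for (si in seq_len(nrow(sheet))) {
        cond <- sheet$condition[si]
        sid <- sheet$sample_id[si]
        usage_prox <- truth[[paste0("usage_proximal_", cond)]][gidx]
        pal_med <- truth[[paste0("pal_median_", cond)]][gidx]

        distal <- runif(N) >= usage_prox
        pas_true <- ifelse(distal, truth$distal_pas[gidx],
                           truth$proximal_pas[gidx])
        jit <- pmax(pmin(round(rnorm(N, 0, config$jitterSd)),
                         config$jitterMax), -config$jitterMax)
        end3 <- as.integer(pas_true + jit)

        complete <- runif(N) < config$completeness[[cond]]
        u_up <- floor(runif(N) * (upmax + 1))          # 0..upmax upstream
        u_fr <- runif(N)                               # truncation fraction
        gap_plus <- pmax(end3 - 50L - cds, 1L)
        gap_minus <- pmax(cds - (end3 + 50L), 1L)
        five <- integer(N)
        five[plus & complete] <- (cds - u_up)[plus & complete]
        five[!plus & complete] <- (cds + u_up)[!plus & complete]
        five[plus & !complete] <-
            (cds + ceiling(u_fr * gap_plus))[plus & !complete]
        five[!plus & !complete] <-
            (cds - ceiling(u_fr * gap_minus))[!plus & !complete]

        astart <- ifelse(plus, five, end3)
        aend <- ifelse(plus, end3, five)

        pal <- round(rlnorm(N, log(pal_med), config$palSdlog), 2)
        fail <- runif(N) < config$qcFailProb
        qc <- rep("PASS", N)
        qc[fail] <- qc_fail_tags[1L +
            (floor(runif(sum(fail)) * length(qc_fail_tags)) %%
             length(qc_fail_tags))]
        read_id <- sprintf("%s_%07d", sid, seq_len(N))

        aln <- data.frame(read_id = read_id, chrom = truth$chrom[gidx],
                          start = astart - 1L, end = aend,
                          strand = truth$strand[gidx],
                          stringsAsFactors = FALSE)
        aln_path <- file.path(dir, paste0(sid, ".alignments.tsv"))
        .writeTsv(aln, aln_path)

        polya <- data.frame(
            readname = read_id, contig = truth$chrom[gidx],
            position = astart - 1L, leader_start = 0L, adapter_start = 0L,
            polya_start = 0L, transcript_start = 0L, read_rate = 70L,
            polya_length = sprintf("%.2f", pal), qc_tag = qc,
            stringsAsFactors = FALSE)
        polya_path <- file.path(dir, paste0(sid, ".polya.tsv"))
        .writeTsv(polya, polya_path)

        paths[paste0(sid, ".alignments")] <- aln_path
        paths[paste0(sid, ".polya")] <- polya_path
        if (emitBam) {
            bam <- .writeSyntheticBam(aln, models,
                                      file.path(dir, paste0(sid, ".bam")))
            paths[paste0(sid, ".bam")] <- bam
        }

        truth_reads[[sid]] <- data.frame(
            read_id = read_id, sample_id = sid, condition = cond,
            replicate = sheet$replicate[si], gene_id = truth$gene_id[gidx],
            pas_site = ifelse(distal, "distal", "proximal"),
            pas_pos_true = as.integer(pas_true), end3 = end3,
            five_prime = five, complete = complete,
            polya_length = pal, qc_tag = qc, stringsAsFactors = FALSE)
    }

    truth_reads <- do.call(rbind, truth_reads)
    rownames(truth_reads) <- NULL
    tr_path <- file.path(dir, "truth_reads.tsv")
    .writeTsv(truth_reads, tr_path)

    sheet_out <- data.frame(
        sample_id = sheet$sample_id, condition = sheet$condition,
        replicate = sheet$replicate,
        alignment_path = paste0(sheet$sample_id,
                                if (emitBam) ".bam" else ".alignments.tsv"),
        polya_path = paste0(sheet$sample_id, ".polya.tsv"),
        stringsAsFactors = FALSE)
    sheet_path <- file.path(dir, "sample_sheet.tsv")
    .writeTsv(sheet_out, sheet_path)
    paths[c("sample_sheet", "truth_reads")] <- c(sheet_path, tr_path)

    list(sampleSheet = sheet_out, truthReads = truth_reads, paths = paths)
}

# SAM -> coordinate-sorted, indexed BAM for one sample
.writeSyntheticBam <- function(aln, models, bamPath) {
    sl <- seqlengths(geneRanges(models))
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                   aln$read_id, ifelse(aln$strand == "+", 0L, 16L),
                   aln$chrom, aln$start + 1L, aln$end - aln$start)
    sam <- tempfile(fileext = ".sam")
    writeLines(c(header, rec), sam)
    on.exit(unlink(sam))
    dest <- asBam(sam, destination = sub("\\.bam$", "", bamPath),
                  overwrite = TRUE, indexDestination = TRUE)
    dest
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running [generateAnnotation()] and [simulateReads()]
#' into one directory: annotation GFF3, per-sample alignment and poly(A)
#' tables (optionally BAM), sample sheet and gene/read truth tables.
#'
#' @param dir Output directory.
#' @param config A [syntheticConfig()]; default scenario when omitted.
#' @param emitBam Also write BAM files (default `FALSE`).
#' @return List with `config`, `models`, `truthGenes`, `truthReads`,
#'   `sampleSheet` and `paths`.
#' @export
simulateScenario <- function(dir, config = syntheticConfig(),
                             emitBam = FALSE) {
    ann <- generateAnnotation(config, dir = dir)
    sim <- simulateReads(config, ann, dir = dir, emitBam = emitBam)
    list(config = config, models = ann$models, truthGenes = ann$truth,
         truthReads = sim$truthReads, sampleSheet = sim$sampleSheet,
         paths = c(ann$paths, sim$paths))
}
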