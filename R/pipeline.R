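# End-to-end pipeline: ingest -> assignment -> PAL -> PAS/APA -> full-length.

#' Pipeline configuration
#'
#' Collects every analysis threshold with its default: clustering gap 24 nt
#' (`maxGap`), cluster support 3 reads (`minSupport`), differential-PAL
#' p-value cutoff 0.05 (`alpha`) and fold change 1.5 (`fcThreshold`, strict),
#' RED cutoff `log2(1.3)` (`redThreshold`, the log2 mapping of a 30% change
#' in relative abundance; set `0.3` for the literal log2-units reading),
#' read floor 10 per condition for PAL testing (`minReads`), full-length
#' slack 0 nt (`slack`) and MAPQ floor 0, i.e. no filter (`minMapq`).
#'
#' @param sampleSheet Path to the sample sheet ([readSampleSheet()]).
#' @param annotation Path to the GFF3 annotation.
#' @param outputDir Directory for the report bundle.
#' @param maxGap,minSupport,alpha,fcThreshold,redThreshold,minReads,slack,minMapq
#'   Analysis thresholds, see description.
#' @param seed Seed echoed into the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sampleSheet, annotation, outputDir,
                           maxGap = 24L, minSupport = 3L, alpha = 0.05,
                           fcThreshold = 1.5, redThreshold = log2(1.3),
                           minReads = 10L, slack = 0L, minMapq = 0L,
                           seed = 1L) {
    cfg <- as.list(environment())
    num <- c("maxGap", "minSupport", "alpha", "fcThreshold",
             "redThreshold", "minReads")
    if (any(unlist(cfg[num]) <= 0))
        stop("thresholds must be positive: ",
             paste(num[unlist(cfg[num]) <= 0], collapse = ", "))
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the [pipelineConfig()] fields as top-level YAML keys; unset keys
#' take their defaults.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- read_yaml(path)
    known <- names(formals(pipelineConfig))
    extra <- setdiff(names(y), known)
    if (length(extra))
        warning("ignoring unknown config key(s): ",
                paste(extra, collapse = ", "))
    do.call(pipelineConfig, y[intersect(names(y), known)])
}

.stageLog <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full 3'-end analysis pipeline
#'
#' Executes ingest, gene assignment, differential PAL, PAS clustering and
#' APA calling, and full-length classification, writing every module's
#' table plus a run manifest into `outputDir`. Exactly two conditions are
#' required. Samples without a poly(A) table are excluded from the PAL and
#' PAS stages with a warning; full-length classification still runs for
#' them.
#'
#' Outputs: `assignment_summary.tsv`, `gene_pal.tsv` (per gene and sample),
#' `differential_pal.tsv`, `pas_clusters.bed`, `apa_results.tsv`,
#' `full_length_reads.tsv`, `full_length_summary.tsv`, `manifest.yaml`.
#'
#' @param config A `PipelineConfig` or path to a YAML config file.
#' @return Invisibly, the report bundle: a list with the data.frames above
#'   plus `clusters` (the cluster experiment), `sampleSheet`, `conditions`,
#'   `manifest` and `outputDir`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "PipelineConfig"))
    t0 <- Sys.time()
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)

    sheet <- readSampleSheet(config$sampleSheet)
    conds <- unique(sheet$condition)
    if (length(conds) != 2L)
        stop("the differential stages need exactly 2 conditions, found ",
             length(conds), ": ", paste(conds, collapse = ", "))
    .stageLog("ingest", "annotation: %s", config$annotation)
    models <- readGeneModels(config$annotation)
    .stageLog("ingest", "%d gene models", length(models))

    readsBySample <- list()
    polyaBySample <- list()
    counts <- list()
    for (i in seq_len(nrow(sheet))) {
        sid <- sheet$sample_id[i]
        reads <- loadAlignments(sheet$alignment_path[i],
                                minMapq = config$minMapq)
        reads <- assignReadsToGenes(reads, models)
        ac <- assignmentCounts(reads)
        has_polya <- nzchar(sheet$polya_path[i]) &&
            file.exists(sheet$polya_path[i])
        if (has_polya) {
            polya <- readPolyATable(sheet$polya_path[i])
            polyaBySample[[sid]] <- polya
            n_pass <- attr(polya, "n_pass")
        } else {
            warning("no poly(A) table for sample ", sid,
                    "; skipping its PAL/PAS contribution")
            n_pass <- NA_integer_
        }
        readsBySample[[sid]] <- reads
        counts[[sid]] <- c(n_reads = length(reads),
                           n_assigned = unname(ac["Assigned"]),
                           n_nofeature = unname(ac["Unassigned_NoFeature"]),
                           n_ambiguity = unname(ac["Unassigned_Ambiguity"]),
                           n_polya_pass = n_pass)
        .stageLog("assign", "%s: %d reads, %d assigned", sid,
                  length(reads), ac["Assigned"])
    }

    assignment <- do.call(rbind, lapply(names(readsBySample), function(s) {
        r <- readsBySample[[s]]
        data.frame(read_id = r$read_id, sample_id = rep(s, length(r)),
                   gene_id = ifelse(is.na(r$gene_id), ".", r$gene_id),
                   status = r$status,
                   overlap_bp = ifelse(is.na(r$overlap_bp), 0L,
                                       r$overlap_bp),
                   stringsAsFactors = FALSE)
    }))

    # reads eligible for PAL/PAS: Assigned AND poly(A) QC PASS
    palSamples <- intersect(names(readsBySample), names(polyaBySample))
    filteredBySample <- lapply(palSamples, function(s) {
        r <- readsBySample[[s]]
        r[r$status == "Assigned" &
          r$read_id %in% polyaBySample[[s]]$read_id]
    })
    names(filteredBySample) <- palSamples
    for (s in palSamples)
        counts[[s]]["n_assigned_pass"] <- length(filteredBySample[[s]])

    genePalTab <- do.call(rbind, lapply(palSamples, function(s) {
        gp <- genePal(palByGene(readsBySample[[s]], polyaBySample[[s]]))
        if (nrow(gp) == 0L) return(NULL)
        cbind(sample_id = s, gp, stringsAsFactors = FALSE)
    }))

    condPals <- lapply(conds, function(cc) {
        ss <- palSamples[sheet$condition[match(palSamples,
                                               sheet$sample_id)] == cc]
        vals <- list()
        for (s in ss) {
            p <- palByGene(readsBySample[[s]], polyaBySample[[s]])
            for (g in names(p)) vals[[g]] <- c(vals[[g]], p[[g]])
        }
        vals
    })
    names(condPals) <- conds
    diffPal <- differentialPal(condPals[[1L]], condPals[[2L]],
                               conditions = conds, alpha = config$alpha,
                               fcThreshold = config$fcThreshold,
                               minReads = config$minReads)
    .stageLog("pal", "%d genes tested, %d significant", nrow(diffPal),
              sum(diffPal$significant))

    if (length(filteredBySample)) {
        clusters <- pasClusterExperiment(filteredBySample, models, sheet,
                                         maxGap = config$maxGap,
                                         minSupport = config$minSupport)
        apa <- callApa(clusters, models, conditions = conds,
                       redThreshold = config$redThreshold,
                       minSupportCondition = config$minSupport)
    } else {
        clusters <- NULL
        apa <- callApa(pasClusterExperiment(
            setNames(list(), character()), models, sheet), models, conds)
    }
    .stageLog("apa", "%d clusters retained, %d genes testable, %d significant",
              if (is.null(clusters)) 0L else nrow(clusters),
              sum(apa$status == "testable"),
              sum(apa$significant %in% TRUE))

    flFlags <- lapply(readsBySample, classifyFullLength, models,
                      slack = config$slack)
    flSummary <- fullLengthSummary(readsBySample, models, sheet,
                                   slack = config$slack)
    flReads <- do.call(rbind, lapply(names(readsBySample), function(s) {
        r <- readsBySample[[s]]
        keep <- !is.na(flFlags[[s]])
        data.frame(read_id = r$read_id[keep],
                   sample_id = rep(s, sum(keep)),
                   gene_id = r$gene_id[keep],
                   full_length = flFlags[[s]][keep],
                   stringsAsFactors = FALSE)
    }))

    out <- config$outputDir
    .writeTsv(assignment, file.path(out, "assignment_summary.tsv"))
    if (!is.null(genePalTab))
        .writeTsv(genePalTab, file.path(out, "gene_pal.tsv"))
    .writeTsv(diffPal, file.path(out, "differential_pal.tsv"))
    if (!is.null(clusters) && nrow(clusters) > 0L)
        exportClustersBed(clusters, file.path(out, "pas_clusters.bed"))
    .writeTsv(apa, file.path(out, "apa_results.tsv"))
    .writeTsv(flReads, file.path(out, "full_length_reads.tsv"))
    .writeTsv(flSummary$perSample,
              file.path(out, "full_length_summary.tsv"))
    .writeTsv(flSummary$perCondition,
              file.path(out, "full_length_by_condition.tsv"))

    manifest <- list(
        package = "drsAPA",
        version = as.character(packageVersion("drsAPA")),
        config = unclass(config),
        inputs = list(
            annotation = unname(md5sum(config$annotation)),
            sample_sheet = unname(md5sum(config$sampleSheet))),
        samples = lapply(counts, as.list),
        genes = list(n_models = length(models),
                     pal_tested = nrow(diffPal),
                     pal_significant = sum(diffPal$significant),
                     apa_reported = nrow(apa),
                     apa_testable = sum(apa$status == "testable"),
                     apa_significant = sum(apa$significant %in% TRUE)),
        elapsed_sec = round(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 2))
    write_yaml(manifest, file.path(out, "manifest.yaml"))

    invisible(list(sampleSheet = sheet, conditions = conds,
                   assignment = assignment, genePal = genePalTab,
                   palByCondition = condPals,
                   differentialPal = diffPal, clusters = clusters,
                   apa = apa, fullLengthReads = flReads,
                   fullLengthSummary = flSummary, manifest = manifest,
                   outputDir = out))
}

#' Condition-level run summary
#'
#' One row per condition: pooled full-length ratio, global median PAL over
#' all contributing reads, the number of genes with a significantly longer
#' PAL in that condition, and the number of genes with a significantly
#' shorter 3' UTR in that condition. With no classifiable data the summary
#' is all-`NA` with a warning.
#'
#' @param bundle The list returned by [runPipeline()].
#' @return data.frame with columns `condition`, `full_length_ratio`,
#'   `global_pal_median`, `n_pal_longer`, `n_apa_shorter`.
#' @export
summarizeRun <- function(bundle) {
    conds <- bundle$conditions
    fl <- bundle$fullLengthSummary$perCondition
    out <- data.frame(condition = conds,
                      full_length_ratio = NA_real_,
                      global_pal_median = NA_real_,
                      n_pal_longer = NA_integer_,
                      n_apa_shorter = NA_integer_,
                      stringsAsFactors = FALSE)
    if (is.null(fl) || nrow(fl) == 0L || all(is.na(fl$ratio))) {
        warning("no classifiable reads; returning all-NA summary")
        return(out)
    }
    out$full_length_ratio <- fl$ratio[match(conds, fl$condition)]
    if (!is.null(bundle$palByCondition)) {
        out$global_pal_median <- vapply(conds, function(cc) {
            v <- unlist(bundle$palByCondition[[cc]], use.names = FALSE)
            if (length(v)) median(v) else NA_real_
        }, numeric(1))
    }
    dp <- bundle$differentialPal
    out$n_pal_longer <- vapply(conds, function(cc)
        sum(dp$significant & dp$direction == cc), integer(1))
    apa <- bundle$apa
    out$n_apa_shorter <- vapply(conds, function(cc)
        sum(apa$significant %in% TRUE &
            apa$direction == paste0("shorter_in_", cc)), integer(1))
    out
}
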