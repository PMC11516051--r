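# The synthetic-data generator: determinism, structural invariants,
# truth-table consistency and statistical honesty.

test_that("fixed seeds give byte-identical outputs", {
    cfg <- syntheticConfig(nGenes = 10L, nChroms = 2L, readsPerGene = 15L,
                           seed = 7L)
    d1 <- file.path(tempdir(), "det1")
    d2 <- file.path(tempdir(), "det2")
    unlink(c(d1, d2), recursive = TRUE)
    simulateScenario(d1, cfg)
    simulateScenario(d2, cfg)
    f1 <- sort(list.files(d1))
    expect_identical(f1, sort(list.files(d2)))
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
})

test_that("generated annotation satisfies the strand conventions", {
    cfg <- syntheticConfig(nGenes = 30L, seed = 13L)
    ann <- generateAnnotation(cfg)
    gm <- ann$models
    expect_true(validObject(gm))  # cds inside an exon etc.
    truth <- ann$truth
    m3e <- most3pExon(gm)
    # truth PAS positions lie on the most-3' exon; for minus-strand genes
    # that is the lowest-coordinate exon
    for (i in seq_len(nrow(truth))) {
        e <- m3e[truth$gene_id[i]]
        expect_true(truth$proximal_pas[i] >= start(e) &&
                    truth$proximal_pas[i] <= end(e))
        expect_true(truth$distal_pas[i] >= start(e) &&
                    truth$distal_pas[i] <= end(e))
        if (truth$strand[i] == "-") {
            ex <- exonsByGene(gm)[[truth$gene_id[i]]]
            expect_equal(start(e), min(start(ex)))
        }
    }
    # both strands and >= 2 exons per gene
    expect_setequal(unique(truth$strand), c("+", "-"))
    expect_true(all(lengths(exonsByGene(gm)) >= 2L))
})

test_that("truth tables account for every read exactly once", {
    d <- file.path(tempdir(), "truthchk")
    unlink(d, recursive = TRUE)
    cfg <- syntheticConfig(nGenes = 8L, nChroms = 2L, readsPerGene = 20L,
                           seed = 3L)
    sc <- simulateScenario(d, cfg)
    sheet <- readSampleSheet(file.path(d, "sample_sheet.tsv"))
    tr <- sc$truthReads
    expect_false(anyDuplicated(tr$read_id) > 0)
    for (i in seq_len(nrow(sheet))) {
        aln <- read.delim(sheet$alignment_path[i])
        expect_setequal(aln$read_id,
                        tr$read_id[tr$sample_id == sheet$sample_id[i]])
        # PASS counts in the table match the truth
        suppressWarnings(pt <- readPolyATable(sheet$polya_path[i]))
        expect_equal(attr(pt, "n_pass"),
                     sum(tr$qc_tag[tr$sample_id == sheet$sample_id[i]] ==
                         "PASS"))
    }
})

test_that("completeness probability one makes every read full-length at slack zero", {
    d <- file.path(tempdir(), "complete1")
    unlink(d, recursive = TRUE)
    cfg <- syntheticConfig(nGenes = 6L, nChroms = 2L, readsPerGene = 25L,
                           replicates = 1L,
                           completeness = c(callus = 1, xylem = 1),
                           seed = 17L)
    sc <- simulateScenario(d, cfg)
    gm <- readGeneModels(file.path(d, "annotation.gff3"))
    sheet <- readSampleSheet(file.path(d, "sample_sheet.tsv"))
    for (i in seq_len(nrow(sheet))) {
        reads <- assignReadsToGenes(loadAlignments(sheet$alignment_path[i]),
                                    gm)
        fl <- classifyFullLength(reads, gm, slack = 0L)
        expect_true(all(fl))
    }
})

test_that("zero jitter lets clustering recover exactly the two truth sites per gene", {
    d <- file.path(tempdir(), "nojitter")
    unlink(d, recursive = TRUE)
    cfg <- syntheticConfig(nGenes = 10L, nChroms = 2L, readsPerGene = 40L,
                           replicates = 1L, jitterSd = 0, jitterMax = 0L,
                           qcFailProb = 0, seed = 23L)
    sc <- simulateScenario(d, cfg)
    tr <- sc$truthReads
    for (gid in unique(tr$gene_id)) {
        pos <- tr$end3[tr$gene_id == gid]
        cl <- clusterPas(pos, maxGap = 24L)
        expect_equal(sort(unique(cl$cluster)), 1:2)
        reps <- sort(unique(cl$position))
        truth <- sc$truthGenes[sc$truthGenes$gene_id == gid, ]
        expect_setequal(reps, c(truth$proximal_pas, truth$distal_pas))
    }
})

test_that("sample medians recover configured PAL targets at depth", {
    # direct Monte-Carlo calibration of the read-level PAL model: medians
    # 80 and 120 nt at 200 reads per gene stay within +-5 nt almost always
    set.seed(29)
    ok <- replicate(200, {
        abs(median(rlnorm(200, log(80), 0.2)) - 80) <= 5 &&
        abs(median(rlnorm(200, log(120), 0.2)) - 120) <= 5
    })
    expect_gte(mean(ok), 0.95)
})

test_that("empirical PAS usage converges to the configured mixture", {
    d <- file.path(tempdir(), "usage")
    unlink(d, recursive = TRUE)
    cfg <- syntheticConfig(nGenes = 20L, readsPerGene = 150L,
                           replicates = 1L, apaShiftFraction = 0.5,
                           seed = 31L)
    sc <- simulateScenario(d, cfg)
    tr <- sc$truthReads
    tg <- sc$truthGenes
    for (i in seq_len(nrow(tg))) {
        for (cond in c("callus", "xylem")) {
            sub <- tr[tr$gene_id == tg$gene_id[i] & tr$condition == cond, ]
            p_emp <- mean(sub$pas_site == "proximal")
            p_cfg <- tg[[paste0("usage_proximal_", cond)]][i]
            se <- sqrt(p_cfg * (1 - p_cfg) / nrow(sub))
            expect_lte(abs(p_emp - p_cfg), 3 * se + 1e-9)
        }
    }
})

test_that("configuration validation rejects impossible scenarios", {
    expect_error(syntheticConfig(pasSeparation = 20L), "24 nt")
    expect_error(syntheticConfig(qcFailProb = 1.5), "probabilities")
    expect_error(syntheticConfig(completeness = c(a = 0.5, b = 0.5)),
                 "named by condition")
    expect_error(
        generateAnnotation(syntheticConfig(nGenes = 100L, nChroms = 1L,
                                           chromLength = 10000L)),
        "chromLength")
})
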