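# PAS extraction, clustering, representative sites, RPM and RED/APA calls.

test_that("a read's PAS is its 3' terminal aligned base, strand-aware", {
    reads <- readsFromTable(data.frame(
        read_id = c("p", "m"), chrom = "chr1",
        start = c(101L, 101L), end = c(600L, 600L),
        strand = c("+", "-")))
    expect_equal(extractReadPas(reads), c(600L, 101L))
    # mirrored genome maps each PAS to its mirror image
    L <- 5000L
    m <- mirrorReads(reads, L)
    expect_equal(extractReadPas(m), L - c(600L, 101L) + 1L)
})

test_that("single-linkage chaining groups the documented examples", {
    pos <- c(rep(100L, 5), rep(110L, 2), 130L, rep(170L, 4))
    cl <- clusterPas(pos, maxGap = 24L)
    expect_equal(split(cl$position, cl$cluster),
                 list(`1` = c(100L, 110L, 130L), `2` = 170L))
    expect_equal(cl$count[cl$position == 100L], 5L)
    # chaining joins 0 and 40 through 20
    cl2 <- clusterPas(c(0L, 20L, 40L), maxGap = 24L)
    expect_equal(unique(cl2$cluster), 1L)
    # singleton and empty input
    expect_equal(nrow(clusterPas(integer(0))), 0L)
    expect_equal(clusterPas(500L)$cluster, 1L)
})

test_that("positions exactly 24 nt apart share a cluster; 25 nt splits", {
    expect_equal(unique(clusterPas(c(100L, 124L))$cluster), 1L)
    expect_equal(clusterPas(c(100L, 125L))$cluster, c(1L, 2L))
})

test_that("clustering equals the transitive-closure oracle and ignores input order", {
    set.seed(77)
    for (i in 1:150) {
        n <- sample(1:50, 1)
        pos <- sample(1:10000, n, replace = TRUE)
        got <- clusterPas(pos, maxGap = 24L)
        want <- clusterOracle(pos, 24L)
        expect_identical(unname(split(got$position, got$cluster)), want)
        got2 <- clusterPas(pos[sample.int(length(pos))], maxGap = 24L)
        expect_identical(got, got2)
    }
})

test_that("representative selection follows abundance, support and the 3' tie-break", {
    r <- selectRepresentative(c(100L, 110L, 130L), c(5L, 2L, 1L), "+")
    expect_equal(r$representative, 100L)
    expect_equal(r$support, 8L)
    expect_true(r$retained)
    # support 2 < 3 is rejected; exactly 3 is retained ("at least three")
    expect_false(selectRepresentative(c(200L, 210L), c(1L, 1L), "+")$retained)
    expect_true(selectRepresentative(c(200L, 210L), c(2L, 1L), "+")$retained)
    # count tie: most 3' in transcription order wins
    expect_equal(selectRepresentative(c(300L, 320L), c(2L, 2L), "+")$representative, 320L)
    expect_equal(selectRepresentative(c(300L, 320L), c(2L, 2L), "-")$representative, 300L)
})

test_that("RPM arithmetic, conservation and scale invariance hold", {
    expect_equal(rpmNormalize(500, 1e6), 500)
    expect_equal(rpmNormalize(1e6, 1e6), 1e6)
    expect_error(rpmNormalize(5, 0), "positive")
    cnt <- matrix(c(30, 10, 25, 15), 2, 2,
                  dimnames = list(NULL, c("s1", "s2")))
    rpm <- rpmNormalize(cnt, c(40, 40))
    expect_equal(colSums(rpm), c(s1 = 1e6, s2 = 1e6))
    # scaling counts and totals together changes nothing
    expect_equal(rpmNormalize(cnt * 7, c(40, 40) * 7), rpm)
    # partial coverage: column sums stay below one million
    expect_true(all(colSums(rpmNormalize(cnt, c(50, 60))) < 1e6))
})

test_that("cluster experiment reproduces per-sample counts and flags the most-3' exon", {
    toy <- apaToyData(
        countsBySample = list(c1_rep1 = c(30L, 10L), c2_rep1 = c(10L, 30L)),
        positions = c(800L, 1000L))
    se <- pasClusterExperiment(toy$reads, toy$models, toy$sheet)
    expect_equal(nrow(se), 2L)
    expect_equal(unname(assay(se, "counts")[, "c1_rep1"]), c(30, 10))
    expect_equal(unname(assay(se, "counts")[, "c2_rep1"]), c(10, 30))
    expect_true(all(rowRanges(se)$on_most3p_exon))
    expect_equal(rowRanges(se)$representative, c(800L, 1000L))
    # below the support floor the cluster disappears
    toy2 <- apaToyData(list(c1_rep1 = c(2L, 10L), c2_rep1 = c(0L, 10L)),
                       positions = c(800L, 1000L))
    se2 <- pasClusterExperiment(toy2$reads, toy2$models, toy2$sheet)
    expect_equal(nrow(se2), 1L)
    expect_equal(rowRanges(se2)$representative, 1000L)
})

test_that("delta RED equals the equivalent two-ratio formulation and the worked example", {
    # proximal/distal usage swap between conditions
    expect_equal(log2(10 / 30), -log2(3), tolerance = 1e-12)
    expect_equal(deltaRed(30, 10, 10, 30), 2 * log2(3), tolerance = 1e-12)
    set.seed(5)
    q <- matrix(runif(4000, 0.01, 1000), ncol = 4)
    lhs <- abs(log2(q[, 2] / q[, 4]) - log2(q[, 1] / q[, 3]))
    rhs <- deltaRed(q[, 1], q[, 2], q[, 3], q[, 4])
    expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("APA calls the injected usage swap with the right direction", {
    toy <- apaToyData(list(c1_rep1 = c(30L, 10L), c2_rep1 = c(10L, 30L)),
                      positions = c(800L, 1000L))
    se <- pasClusterExperiment(toy$reads, toy$models, toy$sheet)
    apa <- callApa(se, toy$models, conditions = c("c1", "c2"))
    expect_equal(apa$status, "testable")
    expect_equal(apa$pPAS, 800L)
    expect_equal(apa$dPAS, 1000L)
    expect_equal(apa$red_1, log2(10 / 30))
    expect_equal(apa$red_2, log2(30 / 10))
    expect_equal(apa$delta_red, 2 * log2(3))
    expect_true(apa$significant)
    expect_equal(apa$direction, "shorter_in_c1")

    # identical usage: delta RED 0, not significant
    null <- apaToyData(list(c1_rep1 = c(20L, 20L), c2_rep1 = c(20L, 20L)),
                       positions = c(800L, 1000L))
    sen <- pasClusterExperiment(null$reads, null$models, null$sheet)
    apan <- callApa(sen, null$models, conditions = c("c1", "c2"))
    expect_equal(apan$delta_red, 0)
    expect_false(apan$significant)
    expect_equal(apan$direction, "none")
})

test_that("condition swap preserves delta RED and flips the direction label", {
    toy <- apaToyData(list(c1_rep1 = c(35L, 12L), c2_rep1 = c(9L, 28L)),
                      positions = c(700L, 950L))
    se <- pasClusterExperiment(toy$reads, toy$models, toy$sheet)
    a <- callApa(se, toy$models, conditions = c("c1", "c2"))
    b <- callApa(se, toy$models, conditions = c("c2", "c1"))
    expect_equal(a$delta_red, b$delta_red)
    expect_equal(a$red_1, b$red_2)
    expect_equal(a$direction, "shorter_in_c1")
    expect_equal(b$direction, "shorter_in_c1")
})

test_that("minus-strand proximal/distal orientation follows transcription order", {
    toy <- apaToyData(list(c1_rep1 = c(30L, 10L), c2_rep1 = c(10L, 30L)),
                      positions = c(300L, 500L), strand = "-")
    se <- pasClusterExperiment(toy$reads, toy$models, toy$sheet)
    apa <- callApa(se, toy$models, conditions = c("c1", "c2"))
    # on '-', the higher coordinate is nearer the stop codon -> proximal
    expect_equal(apa$pPAS, 500L)
    expect_equal(apa$dPAS, 300L)
})

test_that("genes without two usable clusters are reported not-testable", {
    one <- apaToyData(list(c1_rep1 = 40L, c2_rep1 = 40L), positions = 900L)
    se1 <- pasClusterExperiment(one$reads, one$models, one$sheet)
    r1 <- callApa(se1, one$models, conditions = c("c1", "c2"))
    expect_equal(r1$status, "lt2_clusters")
    expect_true(is.na(r1$significant))

    # second cluster present overall but with < 3 reads in one condition
    weak <- apaToyData(list(c1_rep1 = c(30L, 2L), c2_rep1 = c(30L, 2L)),
                       positions = c(700L, 1000L))
    se2 <- pasClusterExperiment(weak$reads, weak$models, weak$sheet)
    r2 <- callApa(se2, weak$models, conditions = c("c1", "c2"))
    expect_equal(r2$status, "insufficient_support")
})

test_that("BED export of clusters is 0-based with pooled support scores", {
    toy <- apaToyData(list(c1_rep1 = c(30L, 10L), c2_rep1 = c(10L, 30L)),
                      positions = c(800L, 1000L))
    se <- pasClusterExperiment(toy$reads, toy$models, toy$sheet)
    p <- file.path(tempdir(), "clusters.bed")
    exportClustersBed(se, p)
    bed <- read.delim(p, header = FALSE)
    expect_equal(bed$V2, start(rowRanges(se)) - 1L)
    expect_equal(bed$V5, c(40L, 40L))
    expect_equal(bed$V6, c("+", "+"))
})
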