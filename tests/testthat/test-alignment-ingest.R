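# Alignment loading and largest-overlap gene assignment.

test_that("TSV dialect is 0-based half-open with strand-aware read ends", {
    p <- writeLinesTo(c("read_id\tchrom\tstart\tend\tstrand",
                        "r1\tchr1\t100\t600\t+",
                        "r2\tchr1\t100\t600\t-"),
                      name = "aln.tsv")
    reads <- loadAlignments(p)
    # 0-based [100, 600) is 1-based [101, 600]
    expect_equal(start(reads), c(101L, 101L))
    expect_equal(end(reads), c(600L, 600L))
    expect_equal(reads$five_prime, c(101L, 600L))
    expect_equal(reads$three_prime, c(600L, 101L))
    # and the writer inverts the reader
    p2 <- file.path(tempdir(), "aln_rt.tsv")
    writeAlignmentsTsv(reads, p2)
    expect_identical(read.delim(p2), read.delim(p))
})

test_that("missing TSV columns are fatal and named", {
    p <- writeLinesTo(c("read_id\tchrom\tstart\tend", "r1\tchr1\t1\t10"),
                      name = "bad_aln.tsv")
    expect_error(loadAlignments(p), "strand")
})

test_that("BAM ingest drops nothing from the generator and matches the TSV path", {
    d <- file.path(tempdir(), "bam_scenario")
    unlink(d, recursive = TRUE)
    sc <- simulateScenario(d, syntheticConfig(nGenes = 6L, nChroms = 2L,
                                              readsPerGene = 25L,
                                              replicates = 1L, seed = 9L),
                           emitBam = TRUE)
    sheet <- readSampleSheet(file.path(d, "sample_sheet.tsv"))
    bam <- sheet$alignment_path[1]
    tsv <- file.path(d, paste0(sheet$sample_id[1], ".alignments.tsv"))
    rb <- loadAlignments(bam)
    rt <- loadAlignments(tsv)
    rb <- rb[order(rb$read_id)]
    rt <- rt[order(rt$read_id)]
    expect_equal(length(rb), length(rt))
    expect_equal(rb$read_id, rt$read_id)
    expect_equal(start(rb), start(rt))
    expect_equal(end(rb), end(rt))
    expect_equal(as.character(strand(rb)), as.character(strand(rt)))
    # read ends equal the generator's latent truth
    truth <- sc$truthReads[match(rb$read_id, sc$truthReads$read_id), ]
    expect_equal(rb$three_prime, truth$end3)
    expect_equal(rb$five_prime, truth$five_prime)
})

test_that("assignment follows largest overlap with strand matching and tie/no-feature rules", {
    gm <- toyGeneModels()  # gA + [101,1100], gB - [2001,3000]
    reads <- readsFromTable(data.frame(
        read_id = c("big", "anti", "tie", "none"),
        chrom = "chr1",
        start = c(701L, 2101L, 901L, 5001L),
        end = c(1300L, 2500L, 1100L, 5100L),
        strand = c("+", "+", "+", "+")))
    # a second + gene overlapping 'tie' by the same 200 bp as gA
    g2 <- GRanges("chr1", IRanges(c(101L, 901L), c(1100L, 1900L)), "+",
                  gene_id = c("gA", "gC"), tx_id = c("gA.t1", "gC.t1"),
                  cds_start = c(151L, 951L))
    ex2 <- GRangesList(
        gA = GRanges("chr1", IRanges(c(101L, 601L), c(400L, 1100L)), "+"),
        gC = GRanges("chr1", IRanges(901L, 1900L), "+"))
    gmc <- GeneModels(g2, ex2)

    a <- assignReadsToGenes(reads, gm)
    expect_equal(a$status,
                 c("Assigned", "Unassigned_NoFeature",
                   "Assigned", "Unassigned_NoFeature"))
    expect_equal(a$gene_id[1], "gA")
    expect_equal(a$overlap_bp[1], 400L)   # [701,1100]
    # 'anti' is antisense to gB: never assigned
    expect_true(is.na(a$gene_id[2]))

    b <- assignReadsToGenes(reads, gmc)
    expect_equal(b$status[3], "Unassigned_Ambiguity")  # 200 bp vs 200 bp
    expect_true(is.na(b$gene_id[3]))
})

test_that("assignment equals the exhaustive oracle and is order invariant", {
    set.seed(404)
    for (trial in 1:40) {
        nG <- sample(3:20, 1)
        nR <- sample(20:120, 1)
        gs <- sort(sample(1:20000, nG))
        genes <- GRanges("chr1",
                         IRanges(gs, gs + sample(200:2000, nG, TRUE)),
                         sample(c("+", "-"), nG, TRUE),
                         gene_id = sprintf("g%02d", seq_len(nG)),
                         tx_id = sprintf("g%02d.t", seq_len(nG)),
                         cds_start = NA_integer_)
        ex <- GRangesList(lapply(seq_len(nG), function(i)
            granges(genes[i])))
        names(ex) <- genes$gene_id
        gm <- GeneModels(genes, ex)
        rs <- sample(1:22000, nR, TRUE)
        reads <- GRanges("chr1", IRanges(rs, rs + sample(50:1500, nR, TRUE)),
                         sample(c("+", "-"), nR, TRUE))
        reads$read_id <- sprintf("r%03d", seq_len(nR))
        reads <- drsAPA:::.annotateReadEnds(reads)

        got <- assignReadsToGenes(reads, gm)
        want <- assignOracle(reads, genes)
        got_lab <- ifelse(got$status == "Assigned", got$gene_id, got$status)
        expect_identical(got_lab, want)

        # partition invariant
        expect_equal(sum(assignmentCounts(got)), nR)

        # shuffling the gene list changes nothing
        perm <- sample(nG)
        got2 <- assignReadsToGenes(reads, gm[perm])
        expect_identical(got2$gene_id, got$gene_id)
        expect_identical(got2$status, got$status)
    }
})

test_that("sample sheets are validated and paths resolved", {
    d <- tempdir()
    writeLines("x", file.path(d, "a.tsv"))
    p <- writeLinesTo(c(
        "sample_id\tcondition\treplicate\talignment_path\tpolya_path",
        "s1\tcallus\t1\ta.tsv\ta.tsv",
        "s2\txylem\t1\ta.tsv\ta.tsv"), dir = d, name = "sheet.tsv")
    sheet <- readSampleSheet(p)
    expect_true(all(file.exists(sheet$alignment_path)))
    dup <- writeLinesTo(c(
        "sample_id\tcondition\treplicate\talignment_path\tpolya_path",
        "s1\tcallus\t1\ta.tsv\ta.tsv",
        "s1\txylem\t1\ta.tsv\ta.tsv"), dir = d, name = "sheet_dup.tsv")
    expect_error(readSampleSheet(dup), "duplicated")
})
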