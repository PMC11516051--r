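# In-code fixtures: tiny gene models, read builders, mirror transforms.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# two-gene toy: one + gene, one - gene, two exons each
toyGeneModels <- function() {
    g <- GRanges(c("chr1", "chr1"),
                 IRanges(c(101L, 2001L), c(1100L, 3000L)),
                 c("+", "-"),
                 gene_id = c("gA", "gB"),
                 tx_id = c("gA.t1", "gB.t1"),
                 cds_start = c(151L, 2900L))
    ex <- GRangesList(
        gA = GRanges("chr1", IRanges(c(101L, 601L), c(400L, 1100L)), "+"),
        gB = GRanges("chr1", IRanges(c(2001L, 2701L), c(2400L, 3000L)), "-"))
    GeneModels(g, ex)
}

# reads from a table of 1-based closed coordinates
readsFromTable <- function(df) {
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), df$strand)
    gr$read_id <- df$read_id
    gr <- drsAPA:::.annotateReadEnds(gr)
    if (!is.null(df$gene_id)) {
        gr$gene_id <- df$gene_id
        gr$status <- ifelse(is.na(df$gene_id), "Unassigned_NoFeature",
                            "Assigned")
        gr$overlap_bp <- ifelse(is.na(df$gene_id), NA_integer_, 1L)
    }
    gr
}

# reflect coordinates through a constant and flip strand
mirrorReads <- function(reads, L) {
    gr <- GRanges(seqnames(reads),
                  IRanges(L - end(reads) + 1L, L - start(reads) + 1L),
                  ifelse(as.character(strand(reads)) == "+", "-", "+"))
    mcols(gr) <- mcols(reads)
    drsAPA:::.annotateReadEnds(gr)
}

mirrorGeneModels <- function(gm, L) {
    g <- geneRanges(gm)
    ex <- exonsByGene(gm)
    flip <- function(s) ifelse(as.character(s) == "+", "-", "+")
    g2 <- GRanges(seqnames(g), IRanges(L - end(g) + 1L, L - start(g) + 1L),
                  flip(strand(g)),
                  gene_id = g$gene_id, tx_id = g$tx_id,
                  cds_start = L - g$cds_start + 1L)
    ex2 <- GRangesList(lapply(seq_along(ex), function(i) {
        e <- ex[[i]]
        sort(GRanges(seqnames(e),
                     IRanges(L - end(e) + 1L, L - start(e) + 1L),
                     flip(strand(e))))
    }))
    names(ex2) <- g2$gene_id
    GeneModels(g2, ex2)
}

# single-exon gene with two PAS clusters; reads stacked at given positions
apaToyData <- function(countsBySample, positions, strand = "+",
                       exonEnd = 1200L) {
    g <- GRanges("chr1", IRanges(1L, exonEnd), strand,
                 gene_id = "g1", tx_id = "g1.t1",
                 cds_start = if (strand == "+") 51L else exonEnd - 50L)
    ex <- GRangesList(g1 = GRanges("chr1", IRanges(1L, exonEnd), strand))
    gm <- GeneModels(g, ex)
    readsBySample <- lapply(countsBySample, function(cnt) {
        pos <- rep(positions, cnt)
        n <- length(pos)
        if (strand == "+") {
            gr <- GRanges("chr1", IRanges(pmax(1L, pos - 150L), pos), "+")
        } else {
            gr <- GRanges("chr1", IRanges(pos, pmin(exonEnd, pos + 150L)),
                          "-")
        }
        gr$read_id <- sprintf("r%04d", seq_len(n))
        gr <- drsAPA:::.annotateReadEnds(gr)
        gr$gene_id <- "g1"
        gr$status <- "Assigned"
        gr$overlap_bp <- width(gr)
        gr
    })
    sheet <- data.frame(sample_id = names(countsBySample),
                        condition = sub("_rep[0-9]+$", "",
                                        names(countsBySample)),
                        replicate = 1L, alignment_path = "",
                        polya_path = "", stringsAsFactors = FALSE)
    list(models = gm, reads = readsBySample, sheet = sheet)
}

writeLinesTo <- function(lines, dir = tempdir(), name = "fixture.txt") {
    p <- file.path(dir, name)
    writeLines(lines, p)
    p
}
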