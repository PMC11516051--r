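# GFF3 in/out for strand-aware gene models.
#
# One representative transcript is kept per gene: the one with the longest
# summed exon length (ties broken by lexicographically smallest transcript
# id). The translation start is the 5'-most CDS base in transcription order.

#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation into a [GeneModels-class] object. Genes may have
#' several transcripts; the representative is the transcript with the longest
#' summed exon length (tie: lexicographically smallest transcript id). The
#' translation start (`cds_start`) is the 5'-most base of the representative
#' transcript's CDS in transcription order: the lowest CDS start on `+`, the
#' highest CDS end on `-`. Exons parented directly on a gene (no mRNA
#' feature) are accepted and treated as an implicit single transcript.
#'
#' Genes lacking exons or CDS features are skipped with a warning. A feature
#' line whose end coordinate is smaller than its start is a fatal error
#' naming the offending line.
#'
#' @param path Path to a GFF3 file (1-based, closed coordinates per the
#'   standard).
#' @return A [GeneModels-class] object.
#' @examples
#' gff <- system.file("extdata", "toy.gff3", package = "drsAPA")
#' if (nzchar(gff)) readGeneModels(gff)
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    .validateGffCoordinates(path)
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)

    genes <- gr[type == "gene"]
    if (length(genes) == 0L) stop("no gene features in ", path)
    gene_ids <- as.character(genes$ID)

    txsel <- type %in% c("mRNA", "transcript")
    tx_id <- as.character(gr$ID[txsel])
    tx_parent <- .firstParent(gr$Parent[txsel])
    tx2gene <- setNames(tx_parent, tx_id)

    children <- gr[type %in% c("exon", "CDS")]
    ch_parent <- .firstParent(children$Parent)
    # exons/CDS parented directly on a gene: implicit transcript per gene
    direct <- ch_parent %in% gene_ids
    implicit <- unique(ch_parent[direct])
    if (length(implicit)) {
        tx2gene <- c(tx2gene, setNames(implicit, paste0(implicit, ".implicit")))
        ch_parent[direct] <- paste0(ch_parent[direct], ".implicit")
    }
    ch_type <- as.character(children$type)

    is_ex <- ch_type == "exon"
    is_cds <- ch_type == "CDS"
    # per-transcript summed exon length; representative = longest, then
    # lexicographically smallest id; transcript must have exon AND CDS
    exlen <- rowsum(width(children)[is_ex], ch_parent[is_ex])
    tx_ok <- intersect(rownames(exlen), unique(ch_parent[is_cds]))
    tx_ok <- tx_ok[tx_ok %in% names(tx2gene)]
    cand <- data.frame(tx = tx_ok, gene = tx2gene[tx_ok],
                       len = exlen[tx_ok, 1L], stringsAsFactors = FALSE)
    cand <- cand[order(cand$gene, -cand$len, cand$tx), , drop = FALSE]
    cand <- cand[!duplicated(cand$gene), , drop = FALSE]

    keep_genes <- gene_ids %in% cand$gene
    if (!all(keep_genes)) {
        warning("skipping ", sum(!keep_genes),
                " gene(s) lacking exon or CDS features: ",
                paste(gene_ids[!keep_genes], collapse = ", "))
    }
    genes <- genes[keep_genes]
    gene_ids <- gene_ids[keep_genes]
    rep_tx <- setNames(cand$tx, cand$gene)[gene_ids]

    sel_ex <- is_ex & ch_parent %in% rep_tx
    ex_gene <- setNames(gene_ids, rep_tx)[ch_parent[sel_ex]]
    exgr <- granges(children[sel_ex])
    mcols(exgr) <- NULL
    o <- order(match(ex_gene, gene_ids), start(exgr))
    ex <- split(exgr[o], factor(ex_gene[o], levels = gene_ids))

    sel_cds <- is_cds & ch_parent %in% rep_tx
    cds_gene <- setNames(gene_ids, rep_tx)[ch_parent[sel_cds]]
    gf <- factor(cds_gene, levels = gene_ids)
    cds_min <- tapply(start(children)[sel_cds], gf, min)
    cds_max <- tapply(end(children)[sel_cds], gf, max)
    plus <- as.character(strand(genes)) == "+"
    cds_start <- as.integer(ifelse(plus, cds_min, cds_max))

    g <- granges(genes)
    mcols(g) <- DataFrame(gene_id = gene_ids,
                          tx_id = unname(sub("\\.implicit$", "", rep_tx)),
                          cds_start = cds_start)
    names(ex) <- gene_ids
    GeneModels(g, ex)
}

# GFF3 column 4/5 sanity scan; names the offending line on failure
.validateGffCoordinates <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "#") & nzchar(lines)
    for (ln in which(body)) {
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 8L)
            stop(sprintf("malformed GFF3 line %d in %s: fewer than 8 fields",
                         ln, path))
        s <- suppressWarnings(as.numeric(f[4L]))
        e <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(s) || is.na(e) || e < s)
            stop(sprintf(
                "malformed coordinates at line %d of %s: start=%s end=%s",
                ln, path, f[4L], f[5L]))
    }
    invisible(TRUE)
}

.firstParent <- function(parents) {
    vapply(as.list(parents),
           function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
}

#' Write gene models as GFF3
#'
#' Emits one gene, one mRNA, the exons and a 3-bp CDS feature marking the
#' start codon for each gene. Reading the file back with [readGeneModels()]
#' reproduces the object field by field. Only the translation start is
#' modelled, so the written CDS spans just the start codon.
#'
#' @param x A [GeneModels-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(x, path) {
    g <- geneRanges(x)
    ex <- exonsByGene(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_along(g)) {
        gid <- g$gene_id[i]
        tid <- g$tx_id[i]
        chrom <- as.character(seqnames(g[i]))
        str <- as.character(strand(g[i]))
        lines <- c(
            sprintf("%s\tdrsAPA\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    chrom, start(g[i]), end(g[i]), str, gid),
            sprintf("%s\tdrsAPA\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    chrom, start(g[i]), end(g[i]), str, tid, gid),
            sprintf("%s\tdrsAPA\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    chrom, start(ex[[i]]), end(ex[[i]]), str, tid))
        cs <- g$cds_start[i]
        if (!is.na(cs)) {
            cds <- if (str == "+") c(cs, cs + 2L) else c(cs - 2L, cs)
            lines <- c(lines, sprintf(
                "%s\tdrsAPA\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                chrom, cds[1L], cds[2L], str, tid))
        }
        writeLines(lines, con)
    }
    invisible(path)
}

#' Export gene models as BED12
#'
#' One BED12 line per gene: blocks are the exons, the thick region marks the
#' start codon (or is empty when no CDS is annotated). BED coordinates are
#' 0-based, half-open.
#'
#' @param x A [GeneModels-class] object.
#' @param path Optional output path; when `NULL` the BED12 data.frame is
#'   returned instead of written.
#' @return The BED12 `data.frame`, invisibly when written to `path`.
#' @export
geneModelsToBed12 <- function(x, path = NULL) {
    g <- geneRanges(x)
    ex <- exonsByGene(x)
    str <- as.character(strand(g))
    cs <- g$cds_start
    thick_start <- ifelse(is.na(cs), start(g) - 1L,
                          ifelse(str == "+", cs - 1L, cs - 3L))
    thick_end <- ifelse(is.na(cs), start(g) - 1L,
                        ifelse(str == "+", cs + 2L, cs))
    bed <- data.frame(
        chrom = as.character(seqnames(g)),
        chromStart = start(g) - 1L,
        chromEnd = end(g),
        name = g$gene_id,
        score = 0L,
        strand = str,
        thickStart = as.integer(thick_start),
        thickEnd = as.integer(thick_end),
        itemRgb = "0,0,0",
        blockCount = lengths(ex),
        blockSizes = vapply(ex, function(e)
            paste0(paste(width(e), collapse = ","), ","), character(1)),
        blockStarts = vapply(seq_along(ex), function(i)
            paste0(paste(start(ex[[i]]) - start(g[i]), collapse = ","), ","),
            character(1)),
        stringsAsFactors = FALSE)
    if (is.null(path)) return(bed)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(bed)
}
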