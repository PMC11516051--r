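#' Gene models for 3'-end analysis
#'
#' A strand-aware container of one representative transcript model per gene:
#' the gene span, its ordered exons, and the genomic position of the first
#' base of the annotated translation start codon. All coordinates follow the
#' GRanges convention (1-based, closed intervals).
#'
#' @slot genes A [GenomicRanges::GRanges] with one range per gene and
#'   metadata columns `gene_id`, `tx_id` (the representative transcript) and
#'   `cds_start` (genomic coordinate of the first base of the start codon in
#'   transcription order; `NA` when no CDS is annotated).
#' @slot exons A [GenomicRanges::GRangesList] named by `gene_id`, holding the
#'   representative transcript's exons sorted by start coordinate.
#'
#' @seealso [readGeneModels()], [most3pExon()], [cdsStart()]
#' @export
setClass("GeneModels",
    slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
    g <- object@genes
    ex <- object@exons
    msgs <- character()
    req <- c("gene_id", "tx_id", "cds_start")
    if (!all(req %in% colnames(mcols(g))))
        return(paste("genes must carry metadata columns:",
                     paste(req, collapse = ", ")))
    ids <- g$gene_id
    if (anyDuplicated(ids)) msgs <- c(msgs, "gene_id values must be unique")
    if (!identical(names(ex), as.character(ids)))
        msgs <- c(msgs, "names(exons) must equal genes$gene_id, in order")
    if (length(msgs)) return(msgs)
    nex <- lengths(ex)
    if (any(nex == 0L))
        msgs <- c(msgs, paste("genes without exons:",
                              paste(ids[nex == 0L], collapse = ", ")))
    ue <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(g), nex)
    bad <- function(cond) unique(ids[grp[cond]])
    mism <- as.character(seqnames(ue)) != as.character(seqnames(g))[grp] |
            as.character(strand(ue)) != as.character(strand(g))[grp]
    if (any(mism))
        msgs <- c(msgs, paste("exon chrom/strand mismatch in:",
                              paste(bad(mism), collapse = ", ")))
    if (length(ue) > 1L) {
        same <- grp[-1L] == grp[-length(grp)]
        disorder <- same & diff(start(ue)) <= 0
        overlap <- same & start(ue)[-1L] <= end(ue)[-length(ue)]
        if (any(disorder))
            msgs <- c(msgs, paste("exons not sorted by start in:",
                paste(unique(ids[grp[-1L][disorder]]), collapse = ", ")))
        if (any(overlap))
            msgs <- c(msgs, paste("overlapping exons in:",
                paste(unique(ids[grp[-1L][overlap]]), collapse = ", ")))
    }
    outside <- start(ue) < start(g)[grp] | end(ue) > end(g)[grp]
    if (any(outside))
        msgs <- c(msgs, paste("exons outside gene span in:",
                              paste(bad(outside), collapse = ", ")))
    cs <- g$cds_start
    has_cs <- which(!is.na(cs))
    if (length(has_cs)) {
        inside <- cs[grp] >= start(ue) & cs[grp] <= end(ue)
        ok <- tapply(inside, factor(grp, levels = seq_along(g)), any)
        ok[is.na(ok)] <- FALSE
        bad_cs <- intersect(has_cs, which(!ok))
        if (length(bad_cs))
            msgs <- c(msgs, paste("cds_start not inside an exon in:",
                                  paste(ids[bad_cs], collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModels object
#'
#' @param genes GRanges of gene spans with metadata columns `gene_id`,
#'   `tx_id`, `cds_start`.
#' @param exons GRangesList of exons, named by `gene_id` and parallel to
#'   `genes`.
#' @return A validated [GeneModels-class] object.
#' @export
GeneModels <- function(genes, exons) {
    new("GeneModels", genes = genes, exons = exons)
}

#' @describeIn GeneModels-class Number of genes.
#' @param x A `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels-class Subset by index, logical vector or gene id.
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "GeneModels", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@genes$gene_id)
    new("GeneModels", genes = x@genes[i], exons = x@exons[i])
})

setMethod("show", "GeneModels", function(object) {
    n <- length(object)
    cat(sprintf("GeneModels with %d gene%s on %d sequence%s\n",
                n, if (n == 1L) "" else "s",
                length(unique(as.character(seqnames(object@genes)))),
                if (length(unique(seqnames(object@genes))) == 1L) "" else "s"))
    if (n > 0L) {
        nex <- lengths(object@exons)
        cat(sprintf("  exons per gene: %d-%d; %d gene%s with annotated CDS start\n",
                    min(nex), max(nex), sum(!is.na(object@genes$cds_start)),
                    if (sum(!is.na(object@genes$cds_start)) == 1L) "" else "s"))
    }
})
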