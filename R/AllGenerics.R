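#' @rdname GeneModels-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("most3pExon", function(x) standardGeneric("most3pExon"))

#' Accessors for GeneModels
#'
#' `geneRanges()` returns the gene-span GRanges; `exonsByGene()` the exon
#' GRangesList; `geneIds()` the gene identifiers; `cdsStart()` a named
#' integer vector of translation-start coordinates (first base of the start
#' codon in transcription order; `NA` when unannotated); `most3pExon()` a
#' GRanges with the terminal exon in transcription order for each gene (the
#' highest-coordinate exon on `+`, the lowest on `-`).
#'
#' @param x A [GeneModels-class] object.
#' @return See description.
#' @name GeneModels-accessors
NULL

#' @rdname GeneModels-accessors
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-accessors
#' @export
setMethod("exonsByGene", "GeneModels", function(x) x@exons)

#' @rdname GeneModels-accessors
#' @export
setMethod("geneIds", "GeneModels", function(x) as.character(x@genes$gene_id))

#' @rdname GeneModels-accessors
#' @export
setMethod("cdsStart", "GeneModels", function(x) {
    setNames(as.integer(x@genes$cds_start), x@genes$gene_id)
})

#' @rdname GeneModels-accessors
#' @export
setMethod("most3pExon", "GeneModels", function(x) {
    if (length(x) == 0L) {
        out <- GRanges()
        return(out)
    }
    idx <- vapply(seq_along(x@exons), function(i) {
        ei <- x@exons[[i]]
        if (as.character(strand(x@genes[i])) == "+") which.max(start(ei))
        else which.min(start(ei))
    }, integer(1))
    out <- unlist(x@exons, use.names = FALSE)[
        cumsum(c(0L, head(lengths(x@exons), -1L))) + idx]
    names(out) <- geneIds(x)
    out$gene_id <- geneIds(x)
    out
})
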