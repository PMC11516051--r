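# Alignment ingest and largest-overlap gene assignment.
#
# DRS reads are sequenced 3'->5' from the poly(A) tail, so the aligned
# strand is the strand of origin; assignment therefore requires the read
# strand to match the gene strand.

#' Load long-read alignments
#'
#' Reads primary alignment records from a coordinate-sorted, indexed BAM
#' file, or from a plain tab-separated table with columns `read_id`,
#' `chrom`, `start`, `end`, `strand` (0-based, half-open coordinates, one
#' row per read). Secondary and supplementary BAM records are dropped, so
#' each read contributes a single alignment span.
#'
#' The returned GRanges (1-based, closed) carries metadata columns
#' `read_id`, `five_prime` and `three_prime`: the genomic coordinates of the
#' read's 5' and 3' terminal aligned bases. On `+` the 5' end is the leftmost
#' aligned base; on `-` it is the rightmost.
#'
#' @param path BAM or TSV file path.
#' @param format `"auto"` (by extension), `"bam"` or `"tsv"`.
#' @param minMapq Minimum mapping quality; records below it are dropped.
#'   Default 0 (no filter). Ignored with a message for TSV input without a
#'   `mapq` column.
#' @return A GRanges of read alignment spans.
#' @export
loadAlignments <- function(path, format = c("auto", "bam", "tsv"),
                           minMapq = 0L) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
                  else "tsv"
    if (!file.exists(path)) stop("alignment file not found: ", path)
    gr <- if (format == "bam") .loadBam(path, minMapq)
          else .loadAlignmentTsv(path, minMapq)
    .annotateReadEnds(gr)
}

.loadBam <- function(path, minMapq) {
    bai <- paste0(path, ".bai")
    bai2 <- paste0(file_path_sans_ext(path), ".bai")
    if (!file.exists(bai) && !file.exists(bai2))
        stop("BAM index not found for ", path,
             "; sort and index first (samtools sort; samtools index)")
    hdr <- scanBamHeader(path)[[1L]]$text
    so <- if (!is.null(hdr[["@HD"]]))
        grep("^SO:", hdr[["@HD"]], value = TRUE) else character()
    if (!length(so) || so != "SO:coordinate")
        stop("BAM not coordinate-sorted: ", path,
             "; run samtools sort before indexing")
    flag <- scanBamFlag(isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE,
                        isUnmappedQuery = FALSE)
    param <- ScanBamParam(flag = flag,
                          mapqFilter = if (minMapq > 0L) minMapq else NA)
    gal <- readGAlignments(path, param = param, use.names = TRUE)
    gr <- granges(gal, use.names = FALSE)
    gr$read_id <- names(gal)
    gr
}

.loadAlignmentTsv <- function(path, minMapq) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("read_id", "chrom", "start", "end", "strand")
    missing_cols <- setdiff(req, colnames(tab))
    if (length(missing_cols))
        stop("alignment TSV ", path, " is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    if (minMapq > 0L) {
        if ("mapq" %in% colnames(tab)) {
            tab <- tab[tab$mapq >= minMapq, , drop = FALSE]
        } else {
            message("minMapq ignored: TSV ", path, " has no mapq column")
        }
    }
    gr <- GRanges(tab$chrom,
                  IRanges(start = tab$start + 1L, end = tab$end),
                  strand = tab$strand)
    gr$read_id <- tab$read_id
    gr
}

.annotateReadEnds <- function(gr) {
    plus <- as.character(strand(gr)) == "+"
    gr$five_prime <- ifelse(plus, start(gr), end(gr))
    gr$three_prime <- ifelse(plus, end(gr), start(gr))
    gr
}

#' Write read alignments in the TSV dialect
#'
#' The inverse of the TSV branch of [loadAlignments()]: columns `read_id`,
#' `chrom`, `start`, `end`, `strand` with 0-based half-open coordinates.
#'
#' @param reads GRanges with a `read_id` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentsTsv <- function(reads, path) {
    tab <- data.frame(read_id = reads$read_id,
                      chrom = as.character(seqnames(reads)),
                      start = start(reads) - 1L,
                      end = end(reads),
                      strand = as.character(strand(reads)),
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assign reads to genes by largest overlap
#'
#' Each read is assigned to the gene whose span it overlaps by the most
#' bases, requiring the read strand to equal the gene strand (DRS preserves
#' strand of origin). Reads overlapping no gene get status
#' `Unassigned_NoFeature`; reads tied for maximal overlap between two or
#' more genes get `Unassigned_Ambiguity`. Overlap is computed against the
#' whole gene span, not the exons, since DRS reads may retain introns.
#'
#' @param reads GRanges from [loadAlignments()].
#' @param geneModels A [GeneModels-class] object.
#' @return `reads` with added metadata columns `gene_id` (NA when
#'   unassigned), `status` (`Assigned`, `Unassigned_NoFeature`,
#'   `Unassigned_Ambiguity`) and `overlap_bp`.
#' @export
assignReadsToGenes <- function(reads, geneModels) {
    genes <- geneRanges(geneModels)
    reads$gene_id <- rep(NA_character_, length(reads))
    reads$status <- rep("Unassigned_NoFeature", length(reads))
    reads$overlap_bp <- rep(NA_integer_, length(reads))
    if (length(reads) == 0L || length(genes) == 0L) return(reads)

    hits <- findOverlaps(reads, genes)  # strand-aware by default
    if (length(hits) == 0L) return(reads)
    qh <- queryHits(hits)
    sh <- subjectHits(hits)
    ov <- width(pintersect(granges(reads)[qh], granges(genes)[sh]))

    ord <- order(qh, -ov, as.character(genes$gene_id)[sh])
    qh <- qh[ord]; sh <- sh[ord]; ov <- ov[ord]
    best <- !duplicated(qh)
    bi <- which(best)
    nxt <- bi + 1L
    tied <- nxt <= length(qh) & qh[pmin(nxt, length(qh))] == qh[bi] &
        ov[pmin(nxt, length(qh))] == ov[bi]

    ridx <- qh[bi]
    reads$overlap_bp[ridx] <- ov[bi]
    amb <- tied
    reads$status[ridx[amb]] <- "Unassigned_Ambiguity"
    reads$status[ridx[!amb]] <- "Assigned"
    reads$gene_id[ridx[!amb]] <- as.character(genes$gene_id)[sh[bi][!amb]]
    reads
}

#' Tabulate assignment statuses
#'
#' @param reads GRanges returned by [assignReadsToGenes()].
#' @return Named integer vector over the three assignment statuses; entries
#'   always sum to `length(reads)`.
#' @export
assignmentCounts <- function(reads) {
    lv <- c("Assigned", "Unassigned_NoFeature", "Unassigned_Ambiguity")
    table(factor(reads$status, levels = lv))
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `condition`, `replicate`,
#' `alignment_path`, `polya_path`. Relative paths are resolved against the
#' sheet's directory. Sample ids must be unique and every condition must
#' have at least one sample.
#'
#' @param path Sample sheet path.
#' @return A data.frame with absolute file paths.
#' @export
readSampleSheet <- function(path) {
    sheet <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("sample_id", "condition", "replicate",
             "alignment_path", "polya_path")
    missing_cols <- setdiff(req, colnames(sheet))
    if (length(missing_cols))
        stop("sample sheet is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("sample sheet has duplicated sample_id values")
    if (any(!nzchar(sheet$condition)))
        stop("sample sheet has empty condition labels")
    base <- dirname(normalizePath(path))
    fix <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                              file.path(base, p), p)
    sheet$alignment_path <- fix(sheet$alignment_path)
    sheet$polya_path <- fix(sheet$polya_path)
    sheet
}
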