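Package: drsAPA
Title: Poly(A) Tail Length and Alternative Polyadenylation Analysis for
    Nanopore Direct RNA Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-condition 3'-end analysis toolkit for nanopore direct RNA
    sequencing (DRS). Ingests gene annotations (GFF3), long-read alignments
    (BAM or a plain tab-separated dialect) and per-read poly(A) tail length
    calls (the nanopolish polya table dialect); assigns reads to genes by
    largest overlap with strand matching; summarises per-gene poly(A) tail
    length (PAL) as the read-level median and calls differential PAL between
    conditions with a rank-sum test and fold-change rule; clusters per-read
    polyadenylation sites (PAS) by single-linkage chaining, selects supported
    representative sites, and calls alternative polyadenylation (APA) on the
    most-3' exon with the relative expression difference (RED) score;
    classifies reads as full-length against annotated translation start
    sites. A synthetic-data generator produces annotation, alignments and
    poly(A) tables with full ground truth for calibration and testing, and a
    pipeline driver orchestrates the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Transcriptomics, LongRead, Sequencing, GeneRegulation,
    AlternativeSplicing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
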