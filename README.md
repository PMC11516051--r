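# drsAPA

3'-end analysis of nanopore direct RNA sequencing (DRS) for two-condition
designs: per-gene poly(A) tail length (PAL) and differential-PAL calling,
polyadenylation-site (PAS) clustering with APA calling via the relative
expression difference (RED) score, and full-length read classification
against annotated translation start sites. It is aimed at transcriptomics
groups comparing an undifferentiated tissue (e.g. callus) with a
differentiated one (e.g. stem-differentiating xylem) from DRS reads that
have already been basecalled, aligned, and run through a poly(A) caller
such as nanopolish `polya`.

## What it computes

For each gene (one representative transcript, strand-aware):

* **PAL** — the median poly(A) length over assigned, QC-PASS reads;
  differential PAL between conditions by a two-sided Wilcoxon rank-sum
  test on read-level tails, called at *p* < 0.05 and median fold change
  strictly > 1.5.
* **PAS / APA** — each read's PAS is its 3' terminal aligned base; sites
  within 24 nt chain into one cluster; clusters need ≥ 3 supporting reads;
  on the most-3' exon the two most abundant clusters define proximal
  (pPAS) and distal (dPAS) sites and, per condition *c* on RPM-normalised
  counts,

  RED_c = log2(dPAS_c / pPAS_c),  ΔRED = |RED_1 − RED_2|,

  with a significant 3'UTR length change when ΔRED > log2(1.3) ≈ 0.3785
  (shorter 3'UTR in the condition with the smaller RED).
* **Full-length ratio** — the fraction of assigned reads whose 5' aligned
  end reaches the gene's start codon (strand-aware, configurable slack).

A synthetic-data generator (`simulateScenario()`) produces GFF3,
alignments (TSV or BAM), nanopolish-dialect poly(A) tables, a sample sheet
and complete ground-truth tables, so every statistic can be validated
against known truth.

## Worked example

```r
library(drsAPA)

dir <- tempfile("drs_demo")
scenario <- simulateScenario(dir, syntheticConfig(seed = 1))

bundle <- runPipeline(pipelineConfig(
    sampleSheet = file.path(dir, "sample_sheet.tsv"),
    annotation  = file.path(dir, "annotation.gff3"),
    outputDir   = file.path(dir, "out")))
summarizeRun(bundle)
```

which prints:

```
  condition full_length_ratio global_pal_median n_pal_longer n_apa_shorter
1    callus            0.8017            106.79           30            58
2     xylem            0.5994            100.06            0            32
```

Reading the table: ~80% of callus reads but only ~60% of xylem reads are
full-length (the generator's completeness probabilities are 0.8 and 0.6);
the global median tail is ~7 nt longer in callus; 30 genes have a
significantly longer PAL in callus and none in xylem (the scenario
injects twofold-longer tails in callus for 15% of 200 genes); and more
genes shorten their 3'UTR in callus (58) than in xylem (32), the injected
APA direction. Per-gene tables (`differential_pal.tsv`,
`apa_results.tsv`, `pas_clusters.bed`, `full_length_summary.tsv`) and a
run manifest with the full filter funnel land in `outputDir`.

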