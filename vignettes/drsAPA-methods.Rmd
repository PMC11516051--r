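---
title: "3'-end analysis of nanopore direct RNA sequencing with drsAPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3'-end analysis of nanopore direct RNA sequencing with drsAPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsAPA)
```

## The problem

Nanopore direct RNA sequencing (DRS) reads native mRNA molecules from the
poly(A) tail towards the 5' cap. Each read therefore carries three signals
that short-read RNA-seq cannot give at single-molecule resolution:

* a **poly(A) tail length (PAL)** estimate, called upstream from the raw
  current signal (e.g. by nanopolish `polya`) and reported per read with a
  QC tag;
* a **polyadenylation site (PAS)**: the genomic coordinate of the read's 3'
  terminal aligned base, i.e. the cleavage/polyadenylation position;
* a **5' completeness** signal: whether the aligned read reaches the
  annotated translation start of its gene, distinguishing full-length
  molecules from truncated (partially degraded or pore-interrupted) ones.

drsAPA compares these three read-level signals between two conditions —
the motivating design is an undifferentiated, regenerable tissue (callus)
against stem-differentiating xylem, with two biological replicates each —
and calls per-gene differential PAL and differential 3'UTR length through
alternative polyadenylation (APA).

## The analysis model, stage by stage

### Gene models

`readGeneModels()` parses a GFF3 annotation. The downstream rules are
defined per gene, not per isoform, so one representative transcript is kept
per gene: the one with the longest summed exon length, ties broken by the
lexicographically smallest transcript identifier. This collapse is a design
decision of this package; any deterministic rule would do, and the choice
only matters for genes whose isoforms disagree about the terminal exon.
Two strand-aware anchors are extracted:

* `cds_start`, the first base of the annotated start codon in
  transcription order (the lowest CDS coordinate on `+`, the highest on
  `-`). Completeness is anchored at the *translation* start, not the
  transcription start, because annotated TSSs are far less reliable in
  non-model genomes and the upstream tooling defines full-length against
  the start codon.
* the **most-3' exon**, the terminal exon in transcription order, on which
  3'UTR APA is assessed.

Coordinates follow the GRanges convention (1-based, closed) everywhere
inside the package; the 0-based, half-open convention appears only in the
external TSV alignment dialect and in BED exports.

### Read ingest and gene assignment

`loadAlignments()` accepts a coordinate-sorted BAM (primary records only;
secondary and supplementary alignments are dropped so each molecule counts
once) or an equivalent five-column TSV. A MAPQ floor is available but off
by default. `assignReadsToGenes()` implements gene-level long-read
counting: a read is assigned to the gene whose *span* it overlaps by the
most bases, with three deliberate properties:

* **gene span, not exon intersection** — DRS reads frequently retain
  introns, and exon-level overlap would punish them;
* **strand matching is mandatory** — DRS is strand-of-origin sequencing,
  and an antisense read's 3' end would contaminate the sense gene's PAS
  set;
* **ties are dropped** (`Unassigned_Ambiguity`), never fractionally
  split — the per-gene statistics downstream need integer read sets.

The three statuses partition the input exactly, which the pipeline
manifest uses as an auditable filter funnel.

### Per-gene PAL and differential PAL

Only reads that are both `Assigned` and QC-`PASS` contribute. The per-gene
PAL is the **median** of its read-level tail lengths (mean of the central
pair for even counts) — medians, because read-level PAL distributions are
right-skewed and heavy-tailed. `differentialPal()` pools replicates within
a condition and compares the two read-level samples with a two-sided
Wilcoxon rank-sum test. A gene is called when `p < 0.05` **and** the
fold change of condition medians **strictly** exceeds 1.5.

Choices worth making explicit:

* The rank-sum test is this package's choice: it is robust to the skew and
  needs no distributional assumption. The normal approximation with
  continuity correction is used by default (`exact = FALSE`); the exact
  small-sample path is available and is verified in the test suite against
  an exhaustive permutation enumeration at 8-vs-8.
* Replicates are pooled before testing; per-replicate medians remain
  available for diagnostics. With two replicates per condition a
  replicate-aware mixed model has essentially no power, and the target
  comparison is tissue-level.
* No multiple-testing correction enters the significance rule (a
  Benjamini–Hochberg column is emitted for convenience). This mirrors the
  raw-p convention of the motivating analysis; users who need FDR control
  should filter on `padj`.
* Genes need `minReads = 10` reads in both conditions to be tested at all;
  genes below the floor are excluded rather than reported non-significant,
  so the denominator of any downstream enrichment is honest.
* A zero median in one condition gives an infinite fold change; such genes
  are flagged `zero_median` for manual review and never auto-called.

### PAS clustering and APA via the RED score

Each read's PAS is its 3' terminal aligned base. Per gene, positions
pooled across all samples are clustered by **single-linkage chaining**: on
the sorted unique positions a new cluster starts wherever the gap to the
previous position exceeds 24 nt. "Within 24 nt of each other" could also
be read as a 24-nt maximum cluster diameter; chaining is the standard
reading in the PAS-clustering literature and is what this package
implements (the gap is a parameter, and positions exactly 24 nt apart
share a cluster). A cluster's reporting site is its most abundant member
position, ties broken toward the most-3' position in transcription order
(the conservative choice: it favours the longer 3'UTR). Clusters need at
least 3 supporting reads in total to be retained, and counts are RPM-
normalised against each sample's total of contributing reads. The RPM
denominator choice is immaterial for APA calls because it cancels inside
the RED ratio below; it only scales the reported RPM columns.

APA is assessed on the most-3' exon only. Among retained clusters whose
representative lies on that exon, the two with the highest pooled RPM are
kept; the one nearer the stop codon in transcription order is the proximal
PAS (pPAS), the farther the distal (dPAS). Per condition
\(c\), with replicate counts pooled,

\[ \mathrm{RED}_c = \log_2\!\frac{\mathrm{dPAS}_c}{\mathrm{pPAS}_c},
\qquad
\Delta\mathrm{RED} = \lvert \mathrm{RED}_1 - \mathrm{RED}_2 \rvert . \]

A gene has a significant 3'UTR length change when
\(\Delta\mathrm{RED} > \log_2(1.3) \approx 0.3785\), and the 3'UTR is
shorter in the condition with the smaller RED. The ">30% change in
relative abundance" rule admits two readings — a 1.3-fold change on the
ratio scale (`log2(1.3)`) or 0.3 log2 units; the package defaults to the
ratio-scale reading and exposes `redThreshold` so the literal 0.3 is one
argument away. Genes with any zero abundance among the four cells are
reported not-testable rather than pseudocounted: no pseudocount is part of
the rule, and an arbitrary one would manufacture infinite-looking shifts
at low counts. The additional requirement of at least 3 reads per chosen
cluster *per condition* protects the ratio from being driven by a single
molecule.

No p-value accompanies \(\Delta\mathrm{RED}\); it is a thresholded effect
size. Its sampling noise under pure multinomial counting is roughly
\(\mathrm{Var}(\widehat{\Delta\mathrm{RED}}) \approx
(1/\ln 2)^2 \sum_{i} 1/n_i\)
over the four counts, so at 50/50 usage the null flag rate stays below 5%
only once each gene has roughly 450+ reads per condition. At shallower
depth the caller is a screen, not a test — this is inherent to the rule,
not to the implementation, and is why the calibration experiments below
use deeper simulated coverage than the default scenario.

### Full-length classification

A read is full-length when its 5' aligned end reaches the translation
start in transcription order: `five_prime <= cds_start + slack` on `+`,
`five_prime >= cds_start - slack` on `-`. `slack` defaults to 0 nt and
exists because completeness rules in the long-read literature differ by a
small tolerance window; increasing it can only move reads from non-full to
full (a monotonicity the tests assert). Reads in genes without an
annotated CDS are excluded from the denominator entirely. Ratios pool
across replicates as summed counts, and `compareFullLength()` offers an
auxiliary two-proportion z-test for the between-condition difference.

## The synthetic scenario

`simulateScenario()` generates the complete input set — GFF3, per-sample
alignment tables (optionally BAM), nanopolish-dialect poly(A) tables, a
sample sheet — together with gene- and read-level truth tables recording
every latent draw. The default scenario is 200 three-exon genes on 4
chromosomes, both strands, 50 reads per gene per sample, two conditions
("callus", "xylem") with two replicates each (~40,000 reads), and
emulates the motivating tissue contrast:

* completeness probability 0.8 (callus) vs 0.6 (xylem);
* per-gene baseline PAL medians log-normal around 100 nt (between-gene
  sdlog 0.25); 15% of genes carry a twofold longer median in callus;
  read-level tails are log-normal with within-gene sdlog 0.20;
* two truth PAS per gene on the most-3' exon, 120 nt apart; null genes use
  them 50/50 in both conditions; 15% of genes shift to 80/20
  proximal-heavy usage in callus (\(\Delta\mathrm{RED} = 2\));
* 3' ends jittered by a rounded normal (sd 3 nt, truncated at ±10 nt), so
  each truth site stays inside a single 24-nt chain and the two sites can
  never merge;
* 5% of reads receive a non-PASS QC tag.

The within-gene sdlog of 0.20 was fixed by a closed-form calibration: the
asymptotic standard error of a sample median, \(1/(2 f(m) \sqrt{n})\),
gives 2.1 nt at a 120-nt median with 200 reads, so targets of 80 and
120 nt are recovered within ±5 nt in well over 95% of genes. That spread
is deliberately *tighter* than typical real DRS tail-length distributions;
together with the absence of mapping error, intron-retention ambiguity,
internal priming and expression imbalance between genes, this means the
recovery rates measured on synthetic data are upper bounds, not forecasts,
for real tissue. What the synthetic results do establish is correctness of
the machinery: the filters, conventions and statistics do exactly what
their definitions say under a model where the truth is known.

Problem sizes used by the validation suite are package choices: the
default 200-gene/40k-read scenario for direction-of-effect and determinism
checks, 100 genes x 100 reads for completeness recovery (10,000 reads per
condition), and 200 genes x 800 reads for APA calibration, the depth at
which the \(\Delta\mathrm{RED}\) null noise sits comfortably below the
log2(1.3) threshold (see the variance formula above).

## Numerical and degenerate-input choices

* Medians use the standard order statistic; no interpolation variants.
* `fold_change = max(medA, medB) / min(medA, medB)` with a separate
  direction label, so the fold-change filter is symmetric in the
  conditions; a condition-label swap provably flips only the label.
* Cluster ranking for APA uses RPM summed across conditions, so library
  depth cannot decide which pair of sites is compared.
* Empty inputs degrade gracefully: empty poly(A) tables yield empty
  streams; a pipeline run over empty read sets returns an all-NA summary
  with a warning and exit status 0; an absurd support threshold empties
  the cluster set without error.
* Everything is deterministic given the inputs; the only randomness in the
  package lives in the generator behind a single seed, and a fixed seed
  reproduces byte-identical files.

## Known limitations

* APA is tested only on the most-3' exon; intronic/internal PAS clusters
  are exported (BED) but never tested.
* Isoform-level PAL and APA are out of scope; the representative-
  transcript collapse hides genuine isoform switching within a gene.
* \(\Delta\mathrm{RED}\) carries no significance test; at the default
  scenario's depth its false-positive rate under the null is materially
  above 5% (see the variance formula), which is why the caller reports
  not-testable states and counts rather than pretending to control error.
* The full-length rule depends entirely on CDS annotation quality, and the
  generator does not emulate 5' adapter artefacts or degradation gradients
  along the gene body.
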