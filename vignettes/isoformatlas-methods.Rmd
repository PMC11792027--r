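---
title: "Methods: long-read isoform refinement and multi-layer differential RNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read isoform refinement and multi-layer differential RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoformatlas)
```

# Overview

Nanopore direct RNA sequencing (DRS) reads full-length transcripts but with
noisy splice boundaries and frequent 5' truncation. `isoformatlas` implements
an integrative refinement strategy: short-read splice junctions sharpen the
splice sites of long reads, and ATAC-seq open-chromatin peaks validate their
transcription start sites. The refined reads are collapsed into a de novo
annotation, which then supports four differential layers between two
conditions (for example fed vs fasting): transcript expression, alternative
splicing, poly(A) tail length, and m6A modification.

All internal coordinates are 0-based half-open (BED-like); GTF input/output
is converted at the boundary. This removes ±1 bookkeeping from every
analysis step, at the cost of one conversion in `read_gtf()`/`write_gtf()`.

# Read refinement

Refinement runs in the order: deletion filter, TSS filter, junction
correction, collapse. The order follows the natural narrative of the method
(cheap per-read filters first, then correction of the survivors); the filters
commute, so the order only affects which stage a doomed read is charged to.

**Deletion filter.** Reads whose summed alignment deletion length exceeds
`max_deletion` = 100 nt are removed (strictly greater; a read at exactly
100 nt survives). Large deletion loads indicate degraded or misaligned reads
whose exon chains cannot be trusted.

**TSS filter.** A read survives only if its strand-aware 5' end (first block
start on `+`, last block end on `-`) lies inside an ATAC-seq peak
(half-open point-in-interval). Peak strand is ignored — open chromatin is
not stranded. An empty peak set removes everything, by design: the filter
asserts positive evidence.

**Junction correction.** Short-read junctions with support below
`min_junction_support` = 3 unique reads are discarded up front. Each read
junction is then snapped to the candidate whose donor *and* acceptor both lie
within `junction_window` = 15 bp. Among candidates the snap target minimizes
`max(|Δdonor|, |Δacceptor|)`; ties break to higher support, then to the
smaller donor coordinate, making correction fully deterministic. A read with
any junction lacking an eligible candidate is rejected, as is a read whose
corrected blocks would contain a zero-length or inverted exon. Rejected
reads are excluded from collapsing and reported by count.

**Collapse.** Multi-exon reads group by exact corrected intron chain;
mono-exonic reads group by single-linkage reciprocal overlap (≥50% of each
read) on the same strand. Groups with fewer than `min_collapse_support` = 3
reads are dropped. Transcript ends are called per side: read ends are
clustered with a gap threshold of `end_cluster_window` = 100 bp, the largest
cluster wins (leftmost on ties), and its rounded median becomes the
transcript end. The end-cluster window and collapse support are exposed as
configuration because upstream long-read collapsers treat them as tunable
defaults. Genes are assembled by single-linkage exon overlap on the same
strand. Transcript and gene identifiers are positional (`iso-00001`,
`gene-0001`, ordered by genomic location) rather than random UUIDs, so a
collapse of the same input is byte-identical — a property the determinism
tests rely on.

# Classification against a reference

`assign_class_codes()` implements a GffCompare-style decision tree with the
code subset the downstream analysis consumes: `=` (identical intron chain),
`c`/`k` (chain containment in either direction), `j` (shared junction),
`e` (mono-exonic query over a reference exon), `i` (inside a reference
intron), `o`/`x` (other same-/opposite-strand exonic overlap) and `u`
(no overlap: novel gene). The rare fuzzy codes (`m, n, s, p, r, y`) are
accepted on input and mapped to categories but never emitted. Categories:
`=` is *matched*; `m, j, o, x, i, y, u` are *different* (novel isoform
structures); `c, k, n, e, s, p, r` are *others* (partial matches). The
explicit code lists define the categories; the prose gloss ("partially
matching splicing sites or no direct overlap") is ambiguous between the two
non-matched groups and is not used.

Two deliberately resolved edge cases:

* Mono-exonic query vs mono-exonic reference: both chains are empty, so
  "identical chain" is vacuous. We call same-strand overlapping mono-exonic
  pairs `=`, which keeps self-comparison an identity (`assign_class_codes(A, A)`
  is all `=`) and mirrors how reference-comparison tools treat single-exon
  matches fuzzily.
* `c`/`k` require a non-empty chain on the contained side, so mono-exonic
  queries fall through to `e` rather than being trivially "contained".

Best-match selection among overlapping references: highest code priority in
the order listed, then longest exonic overlap, then the lexicographically
smallest reference id.

Transcript identity across tissues (`find_tissue_specific()`) is keyed by
`(chrom, strand, intron chain)` only: collapsed transcript ends are
data-dependent, so coordinates of the terminal exons are ignored for
multi-exon models. Mono-exonic models fall back to their exon coordinates.
Dominant transcripts (`find_dominant()`) are the most expressed isoform per
gene; ties break lexicographically and all-zero genes are omitted.

The coding-potential stand-in is a longest-ORF utility: the longest
ATG-initiated reading frame ending at an in-frame stop fully inside the
sequence, length excluding the stop codon, 5'-most on ties. It is a
transparent geometric criterion, not a learned coding-potential model.

# Differential layers

All four layers share one statistical engine: a two-sided Fisher's exact
test on a per-feature 2×2 table, with the standard two-sided rule (sum of
all tables at the observed margins whose probability does not exceed the
observed table's). The package calls `stats::fisher.test`; the test suite
checks it against an independent hypergeometric enumeration for margins up
to 2000.

**Expression** (`fisher_de()`): replicates are pooled by summation, each
feature is tested as `[count_A, rest_A; count_B, rest_B]` against the rest
of the library. Fold change uses pooled CPM with pseudocount 0.01:
`log2((CPM_B + 0.01)/(CPM_A + 0.01))`. A feature is called at
`|log2FC| > 0.5` and `p < 0.01`, both strict. Benjamini–Hochberg q-values
are reported but do not gate calls — the raw-p thresholds define the method;
the q-values are provided for readers who want them. The same function
applies at gene level via `gene_counts()`.

**Splicing** (`enumerate_events()`, `test_events()`): events are derived
from the annotation and quantified through full-length transcript counts —
the long-read advantage — rather than junction-spanning short reads. Seven
types form one unified taxonomy: ES, IR, ALT5, ALT3 (FLAIR diffSplice
style) and AF, AL, MX (SUPPA2 style). Events deduplicate by
`(type, defining coordinates)`; inclusion/exclusion sets are computed over
all isoforms of the gene and are disjoint by construction. Three geometry
decisions matter:

* A block of several exons skipped between the same anchors is one ES event.
* ALT5/ALT3 require the alternative boundary to lie in the *same* flanking
  exon (equal far end). Without this context requirement every
  exon-skipping pair would also emit two spurious ALT events, inflating the
  event set with duplicates of the same biology.
* AF/AL require the rest of the chain to be identical and the terminal
  exons to be non-overlapping, strand-aware (the genomic-last exon is the
  first exon of a `-` transcript).

Events are tested on `[incl_A, excl_A; incl_B, excl_B]` at `p < 0.01`;
PSI = incl/(incl+excl) is reported per condition, and an event with zero
total in a condition is untestable (PSI missing, p = 1).

**Poly(A) tails** (`collect_tails()`, `diff_polya()`): reads below mapping
quality 5 or without a tail estimate are excluded (counted). The shift
statistic is the difference of medians — robust to the right-skewed tail
distributions DRS produces — and the p-value comes from a two-sided
Mann–Whitney U test (Kolmogorov–Smirnov switchable), computed with the
normal approximation for deterministic behavior across sample sizes. A
shift is called at `|Δmedian| > 10` nt and `p < 0.05`, both strict. A
`min_reads` = 10 floor per condition avoids meaningless tests on a handful
of reads; transcripts below it are reported as untestable rather than
silently dropped.

**m6A** (`scan_drach()`, `filter_m6a_sites()`, `diff_m6a()`, `metagene()`):
the site model is count-based — per-site per-sample (modified, total) read
counts are the input contract; signal-level modification inference is out
of scope and replaced by the simulator on the synthetic side. Candidate
sites are every A at position 3 of a DRACH 5-mer (D = A/G/T, R = A/G, A, C,
H = A/C/T) lying entirely within an exon on the matching strand; minus-strand
motifs are matched as their reverse complement on the forward sequence, and
the central A maps to the same forward offset. Regions extend ±10 bp around
the A, clipped at chromosome ends. Sites are kept when coverage ≥5 holds in
at least 2 samples and a modification event (modified > 0 — the package's
reading of "occurring in a sample") also holds in at least 2 samples,
counted over all samples rather than within condition. Differential testing
pools counts per condition, tests `[mod_A, unmod_A; mod_B, unmod_B]`, and
gates at `|log2FC| > 0.5` and `p < 0.01` on modification frequencies with a
pseudo-frequency of 0.01 (mirroring the expression pseudocount; the fold
change needs one to be defined at zero frequency). Metagene positions
rescale transcript coordinates so the 5'UTR spans [0,1), the CDS [1,2) and
the 3'UTR [2,3); a site at the CDS midpoint sits at 1.5 and the first base
of the 3'UTR at exactly 2.0.

# The synthetic-data generator

`simulate_dataset()` emits a complete miniature dataset — genome FASTA,
truth GTF with CDS partitions, spliced-read table, junction support table,
peak BED, m6A counts — with every planted effect recorded in a truth set.
Its defaults are the package's study conditions and are not retuned per
analysis:

* 50 genes with 4–8 exons (150–300 bp, introns 80–400 bp) on 2 chromosomes;
  2–4 isoforms per gene in an exon-skipping dominated structure (each
  alternative isoform skips one distinct internal exon), matching the
  observation that ES is the most common event class in tissue data.
* Two conditions × two pooled pseudo-replicates, a mean of 33 reads per
  transcript per sample (~20k reads per run; the full pipeline completes in
  well under a minute on one core).
* Junction jitter: truncated normal (sd 4), hard-clipped at ±15 bp — inside
  the correction window, so correction can in principle recover every chain.
  5' truncation with probability 0.1 places the read's 5' end at least
  90 bp downstream of the TSS, outside the ±50 bp ATAC peak. 5% of reads
  carry >100 nt of deletions, 5% mapq 0, 5% mapq 1–4.
* Expression effects: 10% of genes are regulated 4-fold in the second
  condition, half up and half down. Bidirectionality keeps the library
  composition balanced; a one-sided effect of this relative magnitude would
  shift every null transcript's CPM and the row-versus-rest Fisher test
  would correctly, but unhelpfully, flag the composition change. All
  isoforms of a regulated gene scale together so isoform proportions (and
  hence PSI) stay fixed, keeping the DE and AS truth layers orthogonal.
* Splicing effects: 12 genes carry a planted exon-skipping shift, PSI
  0.7 → 0.3 (ΔPSI 0.4), at 100 reads per sample (≥200 per condition). The
  isoforms of these genes are also recorded as true DE: a PSI shift at
  constant gene output changes both isoforms' expression by |log2FC| ≈ 1.2.
* Tails: gamma-distributed with per-transcript means uniform in 70–100 nt
  (the range seen across mouse organs) and shape 30 (sd ≈ 15 nt); 10% of
  transcripts gain +20 nt in the second condition. The gamma family is a
  modeling choice for a positive, right-skewed length.
* m6A: 150 DRACH sites sampled from the exonic scan; baseline modification
  fraction 0.10, raised to 0.40 in the second condition at 20% of sites;
  coverage Poisson with mean 50.

The generator is seeded end-to-end: the same seed yields byte-identical
files, and every downstream stage is deterministic (no RNG after
simulation), so full runs hash identically.

**What the simulator does not emulate** — and therefore what passing tests
do not show about real data: base-level sequencing error and basecalling
artifacts; reference bias and multi-mapping in alignment; overlapping or
nested genes; expression-dependent coverage bias along transcripts;
signal-level m6A calling; biological replicate variance beyond Poisson
counting noise (the paper's design pools animals per condition, which the
two pseudo-replicates mirror). Recovery rates on this synthetic data are a
correctness check of the pipeline logic, not an estimate of real-data
sensitivity.

`simulate_tissue_annotations()` supplies the multi-tissue side: per-tissue
annotations sharing a common transcript core with recorded tissue-unique
chains, for exercising tissue-specific transcript detection.

# Numerical choices and degenerate inputs

* Medians of even-sized end clusters round half-to-even (base R `round`).
* All significance gates are strict inequalities, verified at their exact
  boundaries in the tests (deletion 100/101, window 15/16, support 2/3,
  mapq 0/1 and 4/5, coverage 4/5, recurrence 1/2).
* Ties are broken deterministically everywhere: junction snapping by
  support then donor; dominant transcripts and mono-exonic assignment
  lexicographically; end clusters leftmost-largest.
* Degenerate inputs have defined outcomes rather than errors where the
  paper's workflow would simply produce empty output: empty read sets
  collapse to an empty annotation; a feature absent from both conditions
  gets p = 1 and log2FC = 0; events or sites with zero coverage in a
  condition are flagged untestable.
* `fisher.test` on 2×2 tables is exact and fast at the library sizes the
  package targets (tens of thousands of reads); nothing approximates it.

# Problem sizes used by the test suite

The suite exercises the default 50-gene configuration once end-to-end and
smaller 6–20 gene configurations for module-level properties; null
calibration uses 1000 features per layer. These sizes were chosen so the
whole suite documents the method at desk scale while remaining quick to run
during development.

# Known limitations

* The class-code tree emits 9 of GffCompare's 15 codes; annotations relying
  on the fuzzy codes (`m`, `n`, `s`, `p`, `r`, `y`) are categorized but
  such relationships are never produced by the native classifier.
* Mono-exonic read grouping uses a fixed 50% reciprocal-overlap rule; true
  mono-exonic transcript ends are data-dependent and no mode detection
  beyond median clustering is attempted.
* BAM input is not parsed; long reads enter through the neutral TSV dialect
  (one row per read with exon blocks, deletion load, mapq, tail length).
  Converting alignments to that dialect is one `samtools`/awk step away and
  keeps the analysis core free of alignment-format dependencies.
* The Fisher row-versus-rest construction measures *relative* expression;
  strongly unbalanced global regulation between conditions is reported as
  widespread change, which is a property of the method, not a bug in it.
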