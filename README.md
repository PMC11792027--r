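# isoformatlas

Long-read transcriptomes resolve what short-read RNA-seq cannot: which
isoform of a gene a tissue actually expresses, how long its poly(A) tail is,
and where its m6A marks sit. But nanopore direct RNA sequencing (DRS) reads
carry noisy splice boundaries and frequent 5' truncation, so they need
refinement before any of that can be quantified. `isoformatlas` is an R
package for analysts building tissue-specific transcriptome annotations from
DRS and testing condition-dependent RNA regulation (for example fed vs
fasting) at four layers simultaneously.

## What it does

1. **Isoform refinement** — long spliced reads are filtered by alignment
   deletion load (> 100 nt removed), anchored at transcription start sites
   by requiring the 5' end to fall in an ATAC-seq open-chromatin peak,
   corrected against short-read splice junctions (a read splice site is
   valid if a junction with ≥ 3 unique supporting reads lies within
   ±15 bp), and collapsed by exact intron chain into de novo transcript
   models with read support.
2. **Classification** — de novo transcripts are compared to a reference
   annotation with a GffCompare-style class-code scheme; `=` marks matched
   intron chains, `u` marks novel genes, and the codes partition into
   *matched* / *different* / *others*. Tissue-specific transcripts (chains
   present in exactly one tissue), per-gene dominant transcripts, and a
   longest-ORF coding check are derived on top.
3. **Differential layers** — between two conditions, each with pooled
   replicates:
   - *Expression*: per feature, a two-sided Fisher's exact test on
     `[count_A, rest_A; count_B, rest_B]`, with
     `log2FC = log2((CPM_B + 0.01)/(CPM_A + 0.01))`; called at
     `|log2FC| > 0.5`, `p < 0.01`.
   - *Splicing*: events enumerated from the annotation (ES, IR, ALT5, ALT3,
     AF, AL, MX) and tested as `[incl_A, excl_A; incl_B, excl_B]` at
     `p < 0.01`, with PSI = incl/(incl+excl) per condition.
   - *Poly(A)*: per-transcript tail-length distributions (mapq ≥ 5),
     Mann–Whitney U, called at `|Δmedian| > 10` nt, `p < 0.05`.
   - *m6A*: DRACH-motif sites (coverage ≥ 5 in ≥ 2 samples, modified in
     ≥ 2 samples), Fisher on `[mod_A, unmod_A; mod_B, unmod_B]` at
     `|log2FC| > 0.5`, `p < 0.01`, plus metagene positioning over
     5'UTR [0,1), CDS [1,2), 3'UTR [2,3).
4. **Synthetic truth** — a seeded generator (`simulate_dataset()`) produces
   a miniature genome, annotation, reads, junctions, peaks, tails and m6A
   counts with every planted effect recorded, and `evaluate_calls()` scores
   any stage's output as precision/recall against that truth.

Inputs are plain formats: GTF (GENCODE dialect), BED peaks, FASTA, and
neutral TSV tables for spliced reads, junction support and m6A counts.
All internal coordinates are 0-based half-open.

## Worked example

```r
library(isoformatlas)

cfg <- sim_config(n_genes = 20, psi_n_genes = 5, seed = 42)
sim <- simulate_dataset(cfg, "example_run")

reads <- read_reads(sim$paths$reads)                         # 8386 reads
kept  <- filter_by_tss(filter_by_deletion(reads),
                       read_peaks(sim$paths$peaks))          # 7102 survive
corr  <- correct_reads(kept, read_junctions(sim$paths$junctions))
coll  <- collapse_reads(corr[corr$status != "rejected", ])
coll$annotation
#> <tx_annotation> 55 transcripts in 20 genes (0 with CDS)

cls <- assign_class_codes(coll$annotation, sim$truth$annotation)
table(cls$category)
#> matched
#>      55

counts <- quantify(corr[corr$status != "rejected", ], coll$annotation)
de <- fisher_de(counts, c("fed_1", "fed_2"), c("fasting_1", "fasting_2"))
head(de[de$significant, c("id", "cpm_a", "cpm_b", "log2fc", "p_value")], 3)
#>          id cpm_a cpm_b log2fc  p_value
#> 1 iso-00001 33237  8916  -1.90 8.62e-13
#> 2 iso-00002 13103 27027   1.04 6.31e-05
#> 6 iso-00006 36433 12260  -1.57 7.22e-11

ev <- test_events(enumerate_events(coll$annotation), counts,
                  c("fed_1", "fed_2"), c("fasting_1", "fasting_2"))
head(ev[ev$significant, c("event_id", "type", "psi_a", "psi_b", "p_value")], 3)
#>                 event_id type psi_a psi_b  p_value
#> 1    ES:chr1:-:1846-2556   ES 0.717 0.248 4.15e-15
#> 13 ES:chr1:+:32296-33006   ES 0.728 0.315 8.89e-14
#> 16   ES:chr1:+:8033-8749   ES 0.731 0.260 9.41e-18
```

Reading the output: every collapsed transcript here matched a truth intron
chain exactly (category `matched`), the expression layer reports CPM per
condition with the pseudocounted fold change, and the splicing layer finds
the planted exon-skipping shifts — PSI drops from ~0.72 to ~0.27, the
designed ΔPSI of 0.4 under fasting.

The one-call driver `run_pipeline(out_dir, sim_config(seed = 1))` chains
simulate → refine → classify → diffexp → diffsplice → polya → m6a →
evaluate, writes result tables and a JSON manifest under `out_dir`, and
returns the per-layer precision/recall table.

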