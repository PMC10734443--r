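# redoxreg

Analysis pipeline for a bacterial regulatory-mutant RNA-seq study. A
transcription-factor deletion in a purple non-sulfur bacterium
(*Rhodospirillum rubrum*) reshapes expression of the photosynthesis gene
clusters; `redoxreg` provides the statistics to characterize that reshaping
and the supporting genome and phenotype analyses:

- **Differential expression** — a two-condition negative-binomial Wald test
  with median-of-ratios normalization, moderated method-of-moments
  dispersions, and hand-implemented Benjamini-Hochberg adjustment
  (`run_de()`). Fold changes use a signed convention: `fc = -23` means
  23-fold lower in the mutant, and `|fc| >= 1` always.
- **Transcriptional-cluster calling** — candidates (`|fc| >= 2`, raw
  `p < 0.05`) are chained into clusters when consecutive same-strand,
  same-direction candidates are separated by under 250 bp (`call_tcs()`),
  and a rescue rule keeps candidates that fail the BH cut but sit in a
  cluster with a BH-significant member (`apply_rescue()`).
- **Region and category summaries** — fold-change profiles of named genomic
  regions such as photosynthesis gene clusters (`profile_region()`) and
  biological-process breakdowns (`categorize_affected()`).
- **Variant screen** — coverage/frequency filtering, homopolymer-aware
  mutant-vs-parent set difference, and frameshift-consequence prediction by
  translation to the first stop (`filter_variants()`, `unique_to_mutant()`,
  `predict_frameshift()`).
- **Pigmentation phenotype** — the photomembrane production index
  `PMP = OD880/OD660`, its difference to an unpigmented control, growth-curve
  endpoints and pooled-variance t comparisons (`endpoint_summary()`,
  `compare_groups()`).
- **Synthetic data with planted truth** — `sim_config()` /
  `simulate_dataset()` generate annotation, counts, variant tables and
  growth series with known ground truth, so every stage is testable without
  external sequencing data.

See `vignettes/methods.Rmd` for the model, conventions and threshold
rationale.

## Worked example

Simulate a dataset with two planted transcriptional clusters, run the
differential-expression and cluster-calling stages, and summarize:

```r
library(redoxreg)

cfg <- sim_config(
  n_genes = 120,
  planted_clusters = list(list(size = 4, strand = "-", fc = -23),
                          list(size = 3, strand = "+", fc = 4)),
  n_replicates = 4, nb_dispersion = 0.005, seed = 42
)
d      <- gen_annotation(cfg)
counts <- gen_counts(d$annotation, d$truth, cfg)

de   <- run_de(counts)
cand <- select_candidates(de)        # |fc| >= 2 and raw p < 0.05
tcs  <- call_tcs(cand, d$annotation) # chain candidates, gap < 250 bp
aff  <- apply_rescue(de, cand, tcs)  # BH cut + cluster rescue

tcs$tcs[, c("tc_id", "strand", "n_genes", "avg_fc", "members")]
#>    tc_id strand n_genes     avg_fc                                 members
#> 1 TC_001      +       3   3.760755           gene_0045,gene_0046,gene_0047
#> 2 TC_002      -       4 -20.185206 gene_0099,gene_0100,gene_0101,gene_0102

unlist(aff$counts)
#> n_affected     n_down       n_up    n_in_tc      n_tcs  n_rescued
#>          7          4          3          7          2          0
```

Both planted clusters are recovered with their signed fold changes. The
reporting helpers use integer percentages rounded half away from zero, e.g.
for headline counts of 273 affected genes (227 down, 47 up, 153 in clusters):

```r
affected_percentages(n_affected = 273, n_down = 227, n_up = 47, n_in_tc = 153)
#> $pct_down
#> [1] 83
#> $pct_up
#> [1] 17
#> $pct_in_tc
#> [1] 56
```

and the ORF helpers convert reading-frame lengths to protein sizes:

```r
orf_protein_length(546)             # 546 nt ORF
#> [1] 181
round(percent_reduction(218, 181))  # vs a 218 aa homolog
#> [1] 17
```

The full pipeline (simulation or real inputs through DE, clusters, regions,
categories, phenotype and variants, with a manifest) runs from a YAML
configuration via `run_pipeline(read_pipeline_config("config.yaml"))`, or
from the command line with `inst/cli/redoxreg.R`.

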