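---
title: "Methods: differential expression, transcriptional clusters and variant screening in redoxreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, transcriptional clusters and variant screening in redoxreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxreg)
```

`redoxreg` analyzes RNA-seq, genome-resequencing and growth/pigmentation data
for a bacterial regulatory-mutant study: a transcription-factor deletion in a
purple non-sulfur bacterium reshapes expression of the photosynthesis gene
cluster and related operons. The package provides the statistical pipeline
(differential expression, transcriptional-cluster calling, region and
category summaries), a variant screen for mutant-unique genome changes, a
pigmentation phenotype analysis, and a synthetic-data generator with planted
ground truth used to validate every stage.

## Signed fold-change convention

All fold changes are reported on a signed linear scale with magnitude at
least 1: `fc = 2^lfc` when `lfc >= 0` and `fc = -2^(-lfc)` when `lfc < 0`.
A gene 23-fold lower in the mutant is written `fc = -23`, not `0.043`. The
convention makes down- and upregulation symmetric and keeps magnitudes
directly interpretable. `lfc_to_fc()` and `fc_to_lfc()` convert between the
scales; the values `+1` and `-1` both denote "no change" and share
`lfc = 0`.

## Differential expression model

`run_de()` implements a deliberately simple negative-binomial Wald test:

1. **Normalization.** Median-of-ratios size factors
   (`estimate_size_factors()`): each sample's factor is the median across
   genes of its counts divided by the per-gene geometric mean. This assumes
   the majority of genes are unchanged between conditions; simulations that
   plant regulated genes keep the planted fraction well below half for this
   reason.
2. **Dispersion.** A per-gene method-of-moments estimate
   (`estimate_dispersion()`): with `var = mu + d * mu^2`, `d` is estimated
   from the pooled within-condition variance of normalized counts (condition
   means are removed first, so real signal does not inflate `d`). Raw
   per-gene estimates at 3 replicates per condition are extremely noisy, and
   genes whose dispersion is underestimated by chance produce inflated Wald
   statistics; the test is then anti-conservative. By default the estimate is
   therefore *moderated*: every gene's dispersion is floored at the
   across-gene median of the raw estimates. This is a one-line shrinkage rule
   (no trend fitting), it only raises dispersions (never manufactures
   significance), and it brings the empirical type-I error at the 0.05 level
   into the 3-7% range on null simulations, where the unmoderated estimator
   gives roughly 11%. Set `moderate_dispersion = FALSE` for the plain
   per-gene estimator.
3. **Wald test.** The log2 fold change is computed from
   pseudocount-stabilized (`+0.5`) normalized condition means
   (mutant over wild type). The delta-method standard error uses the NB
   variance at those stabilized means, so conditions with all-zero counts
   still get a finite standard error. Two-sided p values come from the
   standard normal. Genes with zero counts in every sample are flagged
   `tested = FALSE`, given p = 1 and excluded from the multiple-testing
   family.
4. **Multiple testing.** Benjamini-Hochberg step-up, implemented directly in
   `bh_adjust()` and cross-checked in the test suite against both
   `p.adjust()` and a brute-force evaluation of the rejection rule on
   exhaustive permutations of small inputs.

## Candidate selection, transcriptional clusters and the rescue rule

Candidates are genes with `|fc| >= 2` (inclusive) and raw `p < 0.05`
(strict). `call_tcs()` groups candidates into transcriptional clusters (TCs):
within each contig and strand, consecutive candidates are chained when the
intergenic gap (`next start - previous end - 1`) is below 250 bp (strict)
and their regulation directions agree. Maximal chains of at least two genes
are TCs; remaining candidates are isolated. Gaps are measured between
consecutive candidates, so a non-candidate gene between two candidates does
not by itself break a chain, but the distance it adds usually does.

The affected set (`apply_rescue()`) is the union of candidates that pass the
BH cut (`adjusted p < 0.05`) and candidates that fail it but sit in a TC
with at least one BH-significant member. The rescue rule encodes the
biological prior that co-located, co-directional expression changes are
unlikely to be noise. Rescued genes always satisfy the raw fold-change and
p-value filters; the rule never reaches outside the candidate set.

Percentages in summaries are integers rounded half away from zero
(`83%` down, `17%` up and `56%` in clusters for the reference counts
273/227/47/153). Note that the reported subgroup counts 227 + 47 = 274
differ by one from the reported total of 273; the percentages are computed
over the reported total as given, and the discrepancy is left as-is rather
than silently repaired.

## Variant screen

`filter_variants()` keeps calls with coverage >= 10 (inclusive) and
alternate-allele frequency > 0.60 (strict). `unique_to_mutant()` takes the
key-based set difference (`contig:pos:ref>alt`) of the filtered mutant and
wild-type tables. When a reference genome is supplied, single-base deletions
inside homopolymer runs are first left-aligned
(`canonicalize_homopolymer_deletions()`), because the same physical deletion
can be spelled at any position in the run. `predict_frameshift()` applies an
edit to a CDS, translates to the first stop codon and reports original and
mutant protein lengths, the percent reduction, and whether the edit is a
frameshift, a non-stop extension, or ambiguous in position due to a
homopolymer (deleting any base of a run yields the identical report, which
the test suite verifies position-by-position). `orf_protein_length()`
implements the `nt/3 - 1` arithmetic (546 nt encodes 181 aa) and
`percent_reduction()` the protein-size comparison (181 aa is 17% smaller
than 218 aa after integer rounding).

## Pigmentation phenotype

The photosynthetic membrane proxy is `PMP = OD880 / OD660`
(`compute_pmp()`), invariant to the optical path-length correction
(`correct_pathlength()`) because the factor cancels in the ratio. The
pigmentation effect is `delta PMP = PMP_condition - PMP_control`
(`compute_delta_pmp()`), with the unpigmented aerobic condition as control.
Endpoints are the maximum OD660 over the series and the PMP at the final
time point (`growth_endpoints()`, `endpoint_summary()`). Group comparisons
use the unpaired two-tailed Student t test with pooled variance
(`compare_groups()`); degenerate all-equal inputs return `t = 0, p = 1`.

## Synthetic-data generator

`sim_config()` + `simulate_dataset()` produce a complete dataset with
planted ground truth: a 1-based, inclusive-coordinate gene annotation on a
linear chromosome in which planted clusters have within-cluster gaps below
250 bp and all other gaps at least 250 bp; NB counts with configurable
dispersion (`nb_dispersion = 0` gives Poisson); variant tables with planted
background, mutant-unique and decoy calls; and logistic growth series with a
planted pigment effect. Streams are independently seeded (annotation,
counts, variants, growth use `seed + 0..3`), so the same seed is fully
reproducible.

The generator emulates the *statistical* structure the pipeline consumes —
gap geometry, NB count noise, screen-failing decoy variants, path-length and
measurement noise — not sequence-level realism: there are no real genome
sequences, no read alignment, and no library-preparation biases.

`exact_counts = TRUE` replaces NB sampling with `round(mu)`, a noise-free
mode used by the recovery benchmark (`recovery_benchmark_config()`): 2000
genes with 40 planted clusters at signed fold changes -83, -23, -4 and +4.
Exact counts make the acceptance properties deterministic, including one
deliberately constructed rescue gene: a cluster member with baseline mean 2
whose mutant counts round to zero, so it passes the raw filters (fc = -5,
p about 0.011) but fails the BH cut and is recovered only through its
BH-significant cluster partners. The -83 clusters are given high baseline
means (500-3000), which both reflects the biology (strongly repressed
photosynthesis genes are highly expressed in the wild type) and keeps the
pseudocount from attenuating extreme fold changes.

## Default thresholds

| Threshold | Default | Rationale |
|---|---|---|
| fold change | `|fc| >= 2` | conventional two-fold screen, inclusive |
| raw p | `< 0.05` | candidate filter, strict |
| BH adjusted p | `< 0.05` | affected-set significance |
| cluster gap | `< 250` bp | operon-scale intergenic distance, strict |
| variant coverage | `>= 10` | minimum read support, inclusive |
| variant frequency | `> 0.60` | near-clonal calls only, strict |

All are arguments to the corresponding functions and keys in the pipeline
YAML configuration (`read_pipeline_config()`, `run_pipeline()`).

## Limitations

The Wald test uses a normal reference distribution with plug-in dispersions;
at 3 replicates per condition its power and calibration are inferior to
established tools (DESeq2, edgeR) and the moderation rule is a floor, not an
empirical-Bayes fit. Median-of-ratios normalization fails when most genes
change. Cluster calling uses annotation geometry only, with no coverage
continuity between genes. The frameshift predictor handles single
substitutions, insertions and deletions within one CDS and does not model
splice or regulatory effects.
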