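# apobec3edit

Detection and cohort-level scoring of APOBEC3-mediated C-to-U RNA editing
from paired RNA and DNA (exome) sequencing evidence.

APOBEC3 cytidine deaminases edit C to U at specific positions of mRNAs.  In
sequencing data an edited position shows a C→T difference (on the
transcribed strand) between a sample's RNA reads and its own DNA reads.
Distinguishing real editing from germline polymorphism, somatic mutation,
sequencing error and alignment artifact requires joint, gated analysis of
both assays.  This package implements such a workflow for cohorts (the
motivating use case is tumor cohorts with paired mRNA-seq and exome data),
for researchers studying RNA editing prevalence and its clinical
correlates.

## The decision tree

For a catalog of editing sites (transcribed-C positions with a known
transcription strand), base calls with phred quality ≥ 20 are counted per
site, sample, assay and read strand.  With *R* the reference base count,
*V* the variant base count and *N* the total call count of the RNA data,
a site–sample pair is processed through ordered gates:

1. *N* < 10 → indeterminable (poor RNA coverage);
2. *R* < 6 for *N* ≤ 20, or *R* < 0.4 *N* for *N* > 20 → indeterminable
   (suggests homozygous DNA polymorphism);
3. *R* < 0.8 *N* → indeterminable (suggests heterozygous polymorphism;
   this gate caps any reportable editing level at 20%);
4. *V* = 1 → indeterminable (singleton variant call);
5. *V* = 0 → level 0 if *R* > 3 × (the site's cohort mean *R*/*V* over
   samples with *V* > 0), else indeterminable;
6. for *V* ≥ 2: DNA coverage < 10 → indeterminable; then a one-sided
   **Boschloo unconditional exact test** comparing variant/reference counts
   of RNA versus DNA must give p ≤ 0.05; then the RNA variant fraction
   *V*/(*R*+*V*) must be ≥ 10× the DNA fraction (or DNA must have *V* = 0);
   for *V* > 2 the variant calls must show no strand bias (> 8× odds ratio
   against reference calls, or two-sided Fisher p ≤ 0.01);
7. all gates passed → **edited**, level = *V*/(*R*+*V*) of RNA.

Per sample, the **editing score** is the fraction of editing-positive sites
among determinable sites (computed only with ≥ 5 determinable sites);
samples with score 0 / > 0 form the editing-low / editing-high groups used
in downstream comparisons (t-tests, exact incidence tests, score–expression
correlations, log-rank/Cox survival).

The Boschloo test (one-sided, Fisher-p ordering statistic, nuisance
supremum on a 999-point grid plus the pooled proportion) is implemented in
C++ and verified against brute-force enumeration.

## Worked example

A synthetic cohort generator emulates paired pileups with germline SNPs,
sequencing error, strand artifacts and known per-pair true editing levels:

```r
library(apobec3edit)
cfg <- simulation_config(n_samples = 100, n_sites = 150, seed = 11)
sim <- simulate_cohort(cfg)
calls <- call_cohort(sim$evidence, sim$sites)
print(attr(calls, "reason_tally"), row.names = FALSE)
#>          status         reason    n
#>  INDETERMINABLE ZERO_CTX_UNMET 8592
#>  INDETERMINABLE    LOW_RNA_COV 3450
#>  INDETERMINABLE    SINGLETON_V 1620
#>  INDETERMINABLE  BOSCHLOO_FAIL  541
#>  INDETERMINABLE    LOW_DNA_COV  299
#>            ZERO             OK  228
#>          EDITED             OK  204
#>  INDETERMINABLE       HET_POLY   52
#>  INDETERMINABLE     DNA_SIGNAL    7
#>  INDETERMINABLE    STRAND_BIAS    6
#>  INDETERMINABLE       HOM_POLY    1
```

Most determinations are indeterminable for want of depth — the expected
behaviour at exome/mRNA-seq coverage — while 204 editing events are called.
Scoring and truth-based evaluation:

```r
tabs <- cohort_tables(calls)
scored <- subset(tabs$sample, !is.na(editing_score))
cat("scored:", nrow(scored), "| high:", sum(scored$group == "HIGH"),
    "| low:", sum(scored$group == "LOW"), "\n")
#> scored: 39 | high: 36 | low: 3

metrics <- evaluate_calls(calls, sim$truth)
#> sensitivity 1.000 (n=204) | level RMSE 0.0277 | score-propensity r 0.74
```

Every edited call here is a truly edited pair (no false positives), the
estimated levels track truth to ~3 percentage points RMSE, and per-sample
scores correlate with the latent editing propensity.  The first edited
calls show the evidence behind each verdict:

```r
head(calls[calls$status == "EDITED",
           c("sample_id", "pos", "level", "R_rna", "V_rna", "R_dna", "V_dna", "boschloo_p")], 3)
#>     sample_id    pos      level R_rna V_rna R_dna V_dna boschloo_p
#> 154     S0002   4000 0.13235294    59     9    29     0 0.02353459
#> 216     S0002  66000 0.18354430   129    29    15     0 0.03320835
#> 271     S0002 121000 0.04235727   520    23   109     0 0.01090830
```

File-based runs (`run_pipeline()`, or `inst/scripts/apobec3edit` from a
shell) read tab-delimited site tables (or BED), samtools-mpileup text or
pre-tabulated count tables, and sample annotations, and write calls,
summaries, association tables and a hash manifest.

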