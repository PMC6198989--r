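# cobindcis

Differential transcription-factor co-binding and cis-causality analysis for
regulatory genomics.

When two transcription factors are ChIP-sequenced in the same cell type, the
loci where their peaks overlap carry information about how the factors
interact: if one factor's binding is systematically stronger than the
other's at shared sites, the two may compete for, or mutually inhibit
binding at, those elements. And when a disease-associated locus contains a
candidate regulatory gene, the direction in which risk alleles move that
gene's expression tells you whether higher expression is protective or
pathogenic. `cobindcis` implements both analyses as a tested, reusable R
pipeline, together with the gene-assignment step that connects peaks to
genes and seeded simulators that generate realistic inputs for validation.

It is aimed at computational biologists working with scored peak sets
(BED6/narrowPeak), cohort genotype + expression tables, and GWAS/eQTL
summary statistics.

## What it computes

**Differential co-binding.** For each pair of overlapping peaks (factor A,
factor B), binding strength is the background-normalized fold change

    nfc = (read_count + c) / (background_count + c)

with pseudocount *c* = 1 and a matched local background of equal length.
The nfc values of each factor are rescaled 0–100 (min–max) across the
jointly bound sites, and a site is called *biased* toward a factor when its
nfc ratio exceeds a threshold (default two-fold, strict). The package
reports the biased/unbiased partition and the split of biased sites between
the factors, plus summit-centered mean-coverage profiles (metaplots).

**Peak-to-gene assignment.** Genes get a basal regulatory domain around the
TSS (5 kb upstream, 1 kb downstream, strand-aware), extended outward up to
1 Mb per side but stopping at the nearest flanking gene's basal domain —
the "basal plus extension" association rule. A peak is assigned to every
gene whose extended domain it overlaps by ≥ 1 bp. Gene-set overlaps are
summarized and tested with a two-sided Fisher exact test against a
user-supplied background universe.

**Cis-causality.** Risk variants near a gene (within 100 kb of the gene
body, GWAS p < 1e-6 by default) are tested against cohort expression two
ways: a single-variant eQTL regression (expression ~ additive dosage), and
a burden regression in which samples sharing an identical local haplotype
profile (their dosage vector over the selected variants) are collapsed,
expression is averaged within profiles, and group mean expression is
regressed on risk-allele burden. Collapsing removes the inter-individual
noise component, sharpening the additive signal in regions of strong LD.

**Effect-size concordance.** GWAS and cis-eQTL summary statistics are
merged at stated thresholds (GWAS p < 1e-4, eQTL p < 0.05), eQTL betas are
harmonized to the GWAS effect allele (sign-flipped for swapped alleles,
irreconcilable variants dropped and counted), and the two beta columns are
correlated (Pearson r, two-sided t-test p, OLS trend line).

**Synthetic data.** `simulate_cobinding()` and `simulate_genetics()`
generate peak sets with planted bias structure and a genotyped cohort with
an additive cis effect, haplotype-shared noise, and summary statistics with
a planted beta–beta correlation — all seeded, with truth tables for
scoring. `run_pipeline()` runs every stage end to end and writes outputs
plus a checksummed manifest.

## Worked example

Using the small synthetic fixture files shipped with the package:

```r
library(cobindcis)
fx <- function(name) system.file("extdata", name, package = "cobindcis")

peaks_a <- attach_counts(read_narrowpeak(fx("synthetic_peaks_a.narrowPeak")),
                         read_tsv_table(fx("synthetic_counts_a.tsv")))
peaks_b <- attach_counts(read_narrowpeak(fx("synthetic_peaks_b.narrowPeak")),
                         read_tsv_table(fx("synthetic_counts_b.tsv")))
joint <- build_joint_sites(peaks_a, peaks_b, bias_threshold = 2)
summarize_bias(joint)
#> Joint-site bias summary
#>   joint sites:  120
#>   biased (>threshold-fold): 76
#>   biased toward A: 47 (62%)
#>   biased toward B: 29 (38%)
```

Of the 120 loci bound by both factors, 76 show a more than two-fold
difference in normalized binding, and those biased sites split 62%/38%
toward factor A — close to the 80 biased sites at a 60/40 split this
fixture was generated with.

```r
dosage   <- read_dosage_tsv(fx("synthetic_dosages.tsv"))
expr     <- read_expression_tsv(fx("synthetic_expression.tsv"))
variants <- read_tsv_table(fx("synthetic_risk_variants.tsv"))
cis      <- select_cis_variants(variants, "chr15", 67358195, 67487533)
groups   <- collapse_by_profile(haplotype_profiles(dosage, cis$variant_id), expr)
burden_regression(groups)
#> Regression of mean expression on risk-allele burden (n = 14)
#>   slope     = 0.3914 (intercept 9.785)
#>   Pearson r = 0.6464
#>   p-value   = 0.0125 (two-sided, t with n-2 df)
```

The 52 samples collapse to 14 distinct haplotype profiles; mean expression
rises by ≈ 0.39 units per risk allele (the fixture plants 0.3), a positive
direction of effect: risk alleles increase expression.

```r
pairs <- merge_summary(read_sumstats_tsv(fx("synthetic_gwas_sumstats.tsv")),
                       read_sumstats_tsv(fx("synthetic_eqtl_sumstats.tsv")))
beta_correlation(pairs)
#> Regression of eQTL beta on GWAS beta (log OR) (n = 60)
#>   slope     = 2.018 (intercept -0.02001)
#>   Pearson r = 0.8315
#>   p-value   = 1.946e-16 (two-sided, t with n-2 df)
```

Disease effect sizes and expression effect sizes of the 60 shared variants
are strongly positively correlated: the alleles that raise expression are
the alleles that raise risk.

## Documentation

The methods vignette (`vignettes/cobinding-causality.Rmd`) describes the
models, the tunable parameters and their defaults, what the simulators do
and do not emulate, and the package's numerical conventions and known
limitations.
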