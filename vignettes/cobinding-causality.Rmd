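---
title: "Methods: differential co-binding, regulatory-domain assignment, and cis-causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-binding, regulatory-domain assignment, and cis-causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobindcis)
```

This vignette documents the statistical procedures `cobindcis` implements,
the modelling assumptions behind them, the parameters a user may want to
change, and the design decisions taken where more than one reasonable
convention exists.

## 1. Differential co-binding at jointly bound sites

### Model

Two ChIP-seq experiments give scored peak sets for factors A and B. At loci
where the two factors' peaks overlap ("joint sites"), we ask whether one
factor binds detectably more strongly than the other. Binding strength at a
peak is quantified as the *background-normalized fold change*

$$\mathrm{nfc} = \frac{n_\mathrm{peak} + c}{n_\mathrm{bg} + c},$$

the ratio of reads in the peak to reads in a matched background region of
equal length, with pseudocount $c = 1$ guarding empty backgrounds. Dividing
by a *local* background (the average of the two immediately flanking windows
of the peak's own length, see `counts_from_coverage()`) is the standard
ChIP-seq normalization: it cancels local chromatin accessibility and
mappability effects that inflate raw read counts, and it makes the measure
insensitive to a global library-size factor (multiplying all of one
factor's peak and background counts by a constant leaves nfc unchanged, up
to the pseudocount).

A joint site is classified as **biased** toward A when
$\mathrm{nfc}_A / \mathrm{nfc}_B > \theta$, toward B when the reciprocal
ratio exceeds $\theta$, and **unbiased** otherwise, with strict
inequalities and $\theta = 2$ by default: a two-fold difference in
normalized binding is treated as the smallest biologically meaningful
asymmetry, comfortably above Poisson counting noise at typical peak depths.
For display, each factor's nfc values are additionally rescaled to a
relative 0–100 scale across the joint-site set.

### Assumptions

* Counting noise is approximately Poisson; at the read depths where peaks
  are called (tens to hundreds of reads) the nfc ratio of a genuinely
  two-to-three-fold-biased site rarely falls on the wrong side of the
  threshold, and an equal-affinity pair of factors produces few biased
  calls. The classification is descriptive — no significance test is
  attached to individual sites (a deliberate non-goal).
* Peaks within one set are non-redundant (true of MACS2 output); the
  package deduplicates only exact coordinate duplicates and never merges
  overlapping peaks within a set.

### Numerical conventions

* **Coordinates** are 0-based half-open (BED). narrowPeak summit offsets
  are converted to absolute positions on load; `-1`/`.` sentinels become
  `NA`.
* **Threshold comparisons are strict** (`>`), both for the bias ratio and
  for peak filtering (`filter_peaks()`), so boundary values are excluded
  predictably. The shipped filter presets are fold change > 5 with
  −log10 q > 10 for the primary factor and liberal/standard/stringent
  pairs (5, 25), (10, 60), (15, 200) for a pooled partner set.
* **0–100 rescaling is min–max** over the joint-site set only, not
  genome-wide and not rank-based: the scale is a display convention scoped
  to the sites being compared, and min–max is the only choice that keeps
  ratios of differences interpretable. The choice is isolated in
  `rescale_0_100()`. Degenerate inputs (all values equal, or fewer than
  two sites) raise an error or, inside `build_joint_sites()`, yield `NA`
  scaled values with a warning — the nfc values and bias labels are
  unaffected.
* **Multi-overlap resolution.** When one peak overlaps several on the
  other side, joint sites are resolved one-to-one greedily by largest
  basepair overlap, ties broken by larger B read count and then leftmost
  coordinate. One joint site per locus keeps biased-site accounting well
  defined; the resolution is deterministic.
* **"Adjacent" sites.** Overlap can be relaxed with a symmetric `slop`
  (default 0); `slop = 1000` reproduces a ±1 kb peak extension. Both the
  raw overlap-pair list and the distinct-peaks-per-set counts are exposed
  (`intersect_intervals()`, `count_distinct_overlapping()`), since the two
  statistics differ whenever one peak overlaps several.
* Chromosome names are compared as exact strings; `normalize_chrom()`
  converts between the "chr1" and "1" dialects.

## 2. Regulatory-domain assignment and gene-set tests

Each gene (one composite TSS per gene id; `collapse_tss()` takes the
5′-most TSS when given isoforms) receives a strand-aware **basal domain**
of 5 kb upstream and 1 kb downstream of the TSS, clipped at position 0.
The basal domain is then **extended** outward up to 1 Mb per side, stopping
early at the nearest flanking gene's basal-domain edge; basal domains are
never truncated by neighbours, and when two basal domains overlap the
extension on that side is zero. Neighbour truncation ignores the
neighbour's strand. A peak is assigned to every gene whose extended domain
it overlaps by at least 1 bp; peaks farther than the maximum extension from
every TSS stay unassigned.

Gene-set overlap between the two factors' assigned genes is summarized as
the shared count and the percentage of set A shared (rounded to the nearest
integer for display), and tested with a **two-sided Fisher exact test** on
the 2×2 in-A × in-B table over a user-supplied background universe. Genes
outside the background are dropped with a warning rather than silently
kept, since keeping them would distort the margins. The package implements
only the association rule and the Fisher test — not a genomic-fraction
binomial enrichment statistic, which would require curated domain data.

## 3. Cis-causality: eQTL and haplotype-collapsed burden regression

Variants are selected on the gene's chromosome within 100 kb of the gene
body with GWAS p strictly below 1e-6, and their effects oriented so
positive betas mean the risk allele increases disease odds
(`orient_to_risk()` flips rows reported on the other allele).

* `single_variant_eqtl()` fits ordinary least squares of expression on
  additive dosage (0/1/2) and reports the slope, Pearson r, and the
  two-sided p from the t distribution with $n-2$ df. Additive coding is
  used throughout; a genotype-class coding would cost a degree of freedom
  at cohort sizes around 50 for little gain.
* `haplotype_profiles()` defines a sample's local haplotype profile as its
  **unphased dosage vector** over the selected variants. Phase is not
  needed for collapsing-and-averaging: two samples with the same dosage
  vector have the same risk-allele burden regardless of phase, and
  requiring phased genotypes would shrink the usable data for no change in
  the statistic. Samples with any missing dosage are dropped with a
  warning, not imputed — at deep-WGS missingness rates imputation would
  add unstated modelling for a handful of calls.
* `collapse_by_profile()` averages expression within identical profiles.
  The rationale: expression noise has a component shared by samples with
  the same local genetic background and a larger individual component
  (biology + technical); averaging within profiles shrinks the individual
  component by each group's size while leaving the genetic signal intact,
  so the burden–expression correlation strengthens. The package's paired
  simulations (see §5) verify this under the default noise model.
* `burden_regression()` regresses group mean expression on burden,
  **unweighted by default** — plain averaging over haplotype groups treats
  each distinct haplotype configuration as one observation of the genetic
  effect. Weighting by group size (`weighted = TRUE`) is available; it
  down-weights rare haplotypes and partially undoes the collapsing
  rationale, which is why it is off by default. Both the OLS slope and
  Pearson r are always reported, because published "regression
  coefficients" for this kind of analysis are sometimes correlation
  coefficients; reporting both removes the ambiguity.

Collapsing conserves the number of samples (sum of group sizes) and the
grand weighted mean of expression; with every sample in its own group the
burden regression reduces exactly to the single-variant eQTL fit. Both
facts are enforced by tests.

## 4. GWAS–eQTL effect-size concordance

`merge_summary()` inner-joins two summary tables on variant id after
applying strict p filters (GWAS p < 1e-4, eQTL p < 0.05), flips the eQTL
beta when its effect allele is the GWAS record's other allele, and drops
(and counts) variants whose alleles match neither way — including
strand-ambiguous A/T and C/G variants whose orientation cannot be resolved
without strand information. Duplicate ids within a table keep the
smallest-p record with a warning. GWAS betas are treated as signed log
odds ratios oriented to the stated effect allele, with no blanket
negation: under that convention a positive correlation means
expression-raising alleles are risk-raising. `beta_correlation()` reports
Pearson r with the two-sided t-based p and the OLS trend line; OLS is used
for the line (a local smoother would not change the correlation statistic,
which is the result). Harmonization is an involution — flipping the
reported allele of every record changes no harmonized product — and r is
invariant to positive affine rescaling of either beta column; both are
tested properties.

## 5. What the simulators emulate, and what they do not

`simulate_cobinding()` lays non-overlapping site loci along two
chromosomes with exponential gaps (mean 2 kb between sites) and peak widths
uniform on 200–500 bp, then draws Poisson counts around a signal model:
background at 0.1 reads/bp of peak length, bound peaks enriched 6-fold,
and the favored factor at a planted biased site enriched a further 3-fold
(so the expected nfc ratio at biased sites is 3, safely above the 2-fold
calling threshold but close enough that a few percent of sites fall on the
wrong side — realistic imperfect recovery). The default configuration
reproduces a full-scale two-factor comparison: 30,392 A peaks, 29,533 B
peaks, 979 joint sites, 583 of them biased with 61.4% (358/583) toward A.
A `control_pair` mode draws both factors from the identical signal model,
emulating an equal-affinity factor pair; the biased fraction it produces
is small and directionally symmetric.

`simulate_genetics()` draws each of 52 samples' genotypes as the sum of
two haplotypes from a pool of 6 distinct profiles over 4 variants — about
the number of distinct cis-haplotypes seen in a 100 kb window — and builds
expression as intercept + 0.3 units per risk allele + group noise
(sd 0.5, shared within identical profiles) + individual noise (sd 0.5).
Summary statistics for 60 shared variants are drawn bivariate-normal with
a planted beta–beta correlation of 0.9 (GWAS beta sd 0.12, eQTL beta sd
0.30), with roughly half the eQTL rows emitted on the opposite allele to
exercise harmonization, plus 20 extra rows per table that fail a p filter
or lack a partner.

Deliberately **not** emulated: linkage-disequilibrium decay within the
window (haplotypes are drawn independently of position), sequence content
and motifs, read mappability structure, overdispersion beyond Poisson
(counts of technical replicates are often negative-binomial), population
structure, and covariate effects (PEER factors, ancestry PCs) that real
eQTL analyses regress out. Passing the plant-recovery suite therefore
shows the estimators are correct and well calibrated under clean additive
structure — it does not show robustness to confounding, LD leakage between
the tested window and distal signals, or count overdispersion.

All generators take an explicit seed, restore the caller's RNG state, and
return truth tables sufficient to score every downstream estimate.

## 6. Validation design and problem sizes

The test suite validates every operation against an independent oracle:
interval intersection against an all-pairs brute force (100 random
instances, up to 500×500 intervals), Fisher p-values against exhaustive
hypergeometric-tail enumeration (universes up to 500 genes, agreement to
1e-10), domain construction against a sorted-edge sweep (30-gene
instances), and the collapsing/merging operations against direct per-key
recomputation. Plant recovery runs the full-scale co-binding simulation
(exact binomial 95% CI check on the biased split), 200 cohort replicates
for sign recovery and the collapsing benefit, 200 replicates for the
concordance correlation, and 500 null replicates for type-I calibration
of the burden regression at α = 0.05. These sizes keep the suite under
a minute while leaving the binomial checks adequately powered.

## 7. Known limitations

* The bias classification is descriptive; with very deep libraries,
  trivially small asymmetries can exceed two-fold in nfc, and with very
  shallow ones real bias can be missed. A count-model significance test is
  out of scope by design.
* The background model needs either a coverage track or precomputed
  counts; peaks without counts cannot enter joint-site analysis.
* Regulatory-domain assignment implements the basal-plus-extension rule
  only; curated domains and enrichment statistics of the full web tool are
  not reproduced, and behaviour for genes with exactly coincident basal
  domains follows the package's documented tie-break rather than any
  external convention.
* The concordance merge joins on variant id by default; a `chrom:pos`
  positional join is available for id-free tables but does not match on
  alleles beyond the usual harmonization. Strand-ambiguous variants are
  dropped, not rescued by frequency matching.
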