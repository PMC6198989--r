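Package: cobindcis
Title: Differential Transcription-Factor Co-Binding and Cis-Causality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two ChIP-seq peak sets at jointly bound loci
    (background-normalized binding signal, 0-100 rescaling, two-fold bias
    classification, summit-centered signal profiles), assigning peaks to genes
    with a basal-plus-extension regulatory-domain rule and testing gene-set
    overlap with Fisher's exact test, and linking disease risk alleles to gene
    expression through single-variant eQTL regression, haplotype-profile
    collapsed risk-allele burden regression, and GWAS-eQTL effect-size
    concordance. Includes seeded synthetic-data generators that emulate the
    statistical structure of ChIP-seq co-binding and cohort genotype-expression
    data so the full pipeline can be exercised and validated without external
    downloads.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
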