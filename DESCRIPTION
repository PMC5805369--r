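Package: tissuescan
Title: Trait-Relevant Tissue Identification from GWAS Summary Statistics with
    Multiple Functional Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers trait-relevant tissues from genome-wide association study
    summary statistics by jointly modelling multiple tissue-specific SNP
    annotations. SNP effect-size variances are modelled as linear functions of
    functional annotations; annotation coefficients are estimated from marginal
    chi-square statistics by generalized estimating equations with a
    block-diagonal linkage-disequilibrium working structure and a robust
    sandwich covariance. Per-tissue multivariate Wald statistics are classified
    into trait-relevant and trait-irrelevant groups with a two-component
    noncentral chi-square mixture fitted by expectation-maximization, and the
    fitted coefficients of the top tissue are reused as SNP weights in a
    weighted sequence-kernel (SKAT-style) SNP-set association test. Includes
    readers for summary-statistics, annotation, peak-track (broadPeak/BED),
    genotype and gene-coordinate tables, quality-control filters, and a
    synthetic-data simulator covering genotypes with block-wise linkage
    disequilibrium, tissue-correlated annotations, annotation-dependent effect
    sizes and marginal association scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
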