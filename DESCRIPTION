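Package: PoolCapQC
Title: Performance Evaluation of Hybrid-Capture Targeted Deep Sequencing with
    Pooled Cell-Line Truth Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality-control and performance-evaluation framework for
    hybrid-capture targeted deep sequencing. Builds expected minor-allele-
    frequency truth sets from pooled cell-line genotypes and mixing ratios,
    catalogues background alleles and estimates background error-rate
    distributions, quantifies sample cross-contamination in multiplexed
    hybrid selection via test/control allele groups, computes read-filter
    breakdowns, seeded in-silico down-sampling, coverage-efficiency and
    saturation curves, and MAF-stratified variant-detection sensitivity and
    multi-library concordance. A seeded synthetic sequencing simulator
    (finite library complexity from input DNA mass, PCR duplication,
    off-target and improper-pair reads, per-base substitution error,
    molecule-level cross-contamination) generates all inputs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Rsamtools
Config/testthat/edition: 3
biocViews: Sequencing, TargetedResequencing, QualityControl, Coverage
RoxygenNote: 7.3.3
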