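Package: nimher
Title: Heritability Partitioning and Fine-Mapping of Neanderthal-Introgressed Variants
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the contribution of Neanderthal-introgressed
    variants (NIMs) to complex-trait variation. Implements annotation-matched
    heritability partitioning with a multi-component method-of-moments
    estimator and block-jackknife uncertainty, the matched-background
    delta-h2 statistic contrasting per-NIM and per-modern-human-SNP
    heritability, MAF/LD-coupled phenotype simulation on synthetic genotype
    panels with introgressed-haplotype block structure, per-NIM association
    scans with LD clumping, sum-of-single-effects fine-mapping with
    credible-NIM post-processing and false-discovery-proportion evaluation,
    random-effects meta-analysis, and greedy tag-SNP array design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, Heritability, GenomeWideAssociationStudy,
    StatisticalMethod, Software
RoxygenNote: 7.3.3
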