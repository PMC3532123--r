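Package: StrandBiasQC
Title: Strand-Bias Scoring and Genotype Quality Control for Short-Read
    Variant Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes three strand-bias scores (SB, GATK-SB and a Fisher
    exact score) from per-position stranded allele counts of Illumina
    short-read variant calls, detects per-strand genotype conflicts, and
    evaluates the effect of strand bias on genotype quality through
    transition/transversion ratios stratified by minor allele frequency and
    variant subset, SNP-chip heterozygous concordance by score quantile,
    novel non-synonymous counts, and quantile-based variant stratification.
    Also quantifies the repeatability of strand bias across samples and
    processing pipelines via pairwise Pearson correlation of score sets, and
    ships a synthetic exome-cohort generator that emulates stranded read
    sampling, injected strand bias and false-positive artifact sites so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: SNP, QualityControl, Sequencing, VariantDetection
RoxygenNote: 7.3.3
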