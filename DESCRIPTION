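Package: ampliclone
Title: Single-Cell Targeted Amplicon Genotyping, Clonal Hierarchies, and
    Genotype-Aware Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-sensitivity single-cell genotyping from targeted cDNA and
    gDNA amplicon sequencing: primer-based read demultiplexing,
    base-quality-filtered allele counting, control-calibrated detection and
    mutation-calling thresholds, integration of parallel genomic-DNA and
    mRNA readouts into per-cell zygosity calls, and clone assignment.
    Clonal hierarchies are inferred by maximum likelihood under a
    false-positive/allelic-dropout error model with loss-of-heterozygosity
    aware allele encoding. Companion single-cell expression utilities cover
    RPKM and library-size normalization with a detection floor, quality
    filters, highly variable gene selection, allelic-dropout and library
    bias estimation, cell-cycle scoring with covariate residualization, and
    a combined Wilcoxon plus Fisher's exact differential-expression test
    with Fisher's-method combination and Benjamini-Hochberg adjustment.
    Seeded simulators for amplicon reads, clonal genotype matrices, and
    expression counts provide ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
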