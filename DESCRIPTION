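Package: hsccycle
Title: Cell-Cycle Staging and Lineage Dissection for Single-Cell HSC
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for single-cell RNA-seq of
    hematopoietic stem cells with ERCC spike-ins: cell-level quality
    control, median-of-ratios size-factor normalization, spike-in
    technical-noise modelling with a chi-squared test for highly
    variable genes, PCA-based reconstruction of cell-cycle progression
    with marker-panel stage assignment and projection of perturbed
    (knockout) populations, hematopoietic lineage subgrouping, and
    from-scratch gene-set enrichment (weighted Kolmogorov-Smirnov GSEA
    with phenotype permutation, and hypergeometric over-representation).
    A seeded synthetic-data generator plants known cell-cycle stage,
    lineage and genotype structure so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
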