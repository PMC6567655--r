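Package: pcalens
Title: Exploratory Principal Component Analysis for RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A scriptable toolkit for exploratory analysis of RNA-seq count
    matrices: median-of-ratios size-factor normalization, variance-reducing
    transformations (shifted log and a closed-form variance-stabilizing
    transformation driven by a fitted dispersion-mean trend), principal
    component analysis of samples and genes with scree data, high-loading
    gene extraction, biplot coordinates and two-factor stacked PCA, dataset
    overview summaries (library sizes, detected genes, sample distances and
    correlations, per-gene grouped statistics), functional annotation of
    principal components by hypergeometric GO over-representation per
    component and direction, negative-binomial simulators with planted
    structure for testing, and a reproducible session archive with templated
    HTML report generation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
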