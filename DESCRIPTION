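Package: txnoise
Title: Transcriptional Noise and Aging Analysis for Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative core of an aging single-nucleus RNA-seq analysis:
    quality-control filtering of nuclei, marker-based cell-type annotation,
    a transcriptional-noise statistic based on equal-depth UMI down-sampling
    and Euclidean distance to cell-type group means, Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction, bin-matched
    control-gene module scoring of gene sets, cell-cycle phase assignment,
    and a permutation ligand-receptor interaction test with young/aged
    lost-gained-shared classification. Includes a seeded negative-binomial
    simulator with planted cell types, differential genes, dispersion
    inflation and ligand-receptor activity for parameter-recovery testing,
    plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
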