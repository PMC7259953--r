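Package: yeastlag
Title: Single-Cell Transcriptome Heterogeneity Analysis for Yeast
    Carbon-Source Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for droplet-based single-cell RNA-seq of
    budding yeast populations shifting between carbon sources. Provides UMI
    count-matrix input/output (Matrix Market triplets), cell quality control
    by detected-gene and mitochondrial-read thresholds, depth normalization,
    pseudobulk-versus-bulk concordance, marker-panel cell classification,
    Wilcoxon rank-sum differential expression with fold-change and FDR
    gates, co-expression network construction with Bonferroni-corrected edge
    filtering and module clustering, PCA + k-means subpopulation discovery,
    a micro-colony lag-time relatedness test, and a synthetic droplet data
    generator (negative-binomial counts, ambient mRNA, doublets, empty
    droplets, colony-structured lag times) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
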