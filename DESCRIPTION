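Package: netwasr
Title: Tissue-Network Reprioritization of Gene-Level GWAS Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-phase analysis of quantitative-trait GWAS results. Phase I
    computes LD-aware gene-based association p-values by assigning SNPs to
    genes within a +/-50 kb window and combining per-SNP chi-square
    statistics against a multivariate-normal Monte Carlo null (a VEGAS-style
    test). Phase II performs a network-wide association study (NetWAS):
    a linear support-vector classifier is trained on a tissue-specific
    functional network using nominally significant genes as positives,
    re-ranking all genes by decision value across repeated cross-validation
    draws, with summed-rank aggregation and a permuted-label null. Includes
    a synthetic-data generator (genotypes with block LD, overlapping gene
    clusters, a network with an embedded disease module, a gold standard),
    ROC/AUC evaluation with bootstrap confidence intervals, genomic-inflation
    QQ diagnostics, and a multi-mapping diagnostic for overlapping genes that
    share significant SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
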