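Package: rcclust
Title: Recursive Consensus Clustering of Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of multi-level sample subgroups in
    normalized, log2-transformed expression matrices. At every level of a
    divisive recursion the method re-selects the most variant genes,
    z-scales them, runs eight subsampled consensus k-means processes over a
    grid of item/feature sampling fractions, and chooses the number of
    clusters from the consensus CDF geometry (line length and slope),
    intra-cluster stability, inter-cluster overlap, and a differential-
    expression validity filter, with a frequency vote across processes.
    Includes marker-gene detection with FDR control, single-sample gene-set
    enrichment scores, Fisher cluster-attribute enrichment, Kaplan-Meier
    cluster-survival comparison, cluster-stability diagnostics (adjusted
    Rand index, consensus of runs), tracking and annotation plots, and a
    synthetic-data generator with known group structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    pheatmap,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
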