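Package: quiescr
Title: Dual-Route Discovery of a Shared Quiescence Transcriptional Signature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to identify a quiescent-cell transcriptional signature
    shared across tumor types from bulk RNA-seq count matrices. Implements a
    samples-as-variables correlation PCA with unsupervised detection of the
    phenotype-discriminating component, a moderated log-fold-change
    differential expression route with mean-variance trend shrinkage, overlap
    statistics (relative risk, hypergeometric and permutation tests),
    preranked gene-set enrichment with a permutation null, and thresholded
    Pearson co-expression networks with betweenness/clustering-based rewiring
    comparison between cell states. A negative-binomial simulator generates
    count matrices with planted signatures and state-specific co-expression
    modules so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests:
    fgsea,
    igraph,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
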