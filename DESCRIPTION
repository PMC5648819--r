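Package: mirnet
Title: Mutual-Information Regulatory Networks from Paired miRNA and mRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microRNA-mRNA co-expression networks from paired
    tumour/control expression matrices using a Gaussian-kernel mutual
    information estimator on rank-transformed abundances, class-specific
    percentile thresholds and data-processing-inequality pruning. Includes
    count filtering and TMM / upper-quartile normalization, network topology
    analytics (hubs, first neighbours, kind-removal disintegration, network
    intersection), paired differential expression with a twofold /
    FDR < 0.01 decision rule, hypergeometric gene-set and positional
    (genomic-cluster) enrichment, principal-curve pathway deregulation
    scores, and a negative-binomial synthetic-data generator with planted
    network structure for end-to-end recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    xml2,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
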