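Package: padnet
Title: Pathway-Drug Network Propagation for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disease-specific pathways by gene set enrichment
    analysis (weighted Kolmogorov-Smirnov running sum with phenotype or
    gene-set permutation nulls) across multiple case/control expression
    datasets, builds a weighted pathway-drug bipartite network from
    per-drug pathway enrichment scores, scores repositioning candidates by
    semisupervised label propagation over the symmetrically normalized
    network, selects candidates by Gaussian tail probabilities of
    Z-normalized propagation scores, and triages them on a heterogeneous
    drug-gene validation network using degree centrality, betweenness and
    PageRank. Includes a synthetic-data generator with planted signal for
    end-to-end evaluation, readers and writers for GMT, CLS, GCT and TSV
    formats, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
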