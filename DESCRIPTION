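Package: stagenet
Title: Stagewise Co-Expression Networks, Rewiring and Guided Pathway Walks for Multi-Stage Disease Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for multi-stage (e.g. pre-symptomatic versus
    symptomatic) disease transcriptomics. Provides stagewise differential
    expression with empirical-Bayes moderated t-statistics and top-k
    over/under selection, per-stage gene co-expression network inference via
    k-nearest-neighbour mutual information and the context likelihood of
    relatedness (CLR) background correction, network topology summaries,
    a multi-state node rewiring score over the union (central reference)
    network, hypergeometric over-representation analysis with
    complementary-pathway completion and edge-betweenness pathway
    clustering, guided random-walk pathway ranking with an odds-ratio
    adjustment against a non-guided baseline, and pathway-metabolite set
    logic (exclusive/common partitions and bipartite networks). Includes a
    synthetic-data generator with planted differential expression,
    co-expression modules, a rewired hub and stage-relevant pathways so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
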