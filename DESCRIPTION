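Package: boolhub
Title: Boolean Implication Networks and Hub-Gene Centrality Analysis for
    Multi-Omics Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs Boolean implication networks from ternarized copy-number,
    mRNA and protein expression matrices, quantifies seven graph-centrality
    metrics per gene (degree, in-/out-degree, eigenvector, betweenness,
    closeness, VoteRank), correlates centralities genome-wide with tumor
    versus normal-adjacent-tissue differential expression, CRISPR/RNAi
    dependency scores and univariate Cox hazard ratios, tests gene sets
    against random-set centrality nulls, and selects top-decile hub genes.
    Ships a synthetic multi-omics cohort generator with planted regulatory
    hubs, oncogenes, essential genes and survival hazard genes so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
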