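Package: bnprune
Title: Bayesian Network Structure Learning via Pruning of Candidate Parent Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-based structure learning for discrete Bayesian networks.
    Scores candidate parent sets with the BDeu marginal likelihood, prunes
    them by the subset-score dominance ("legality") rule and by percentage
    pruning of the sorted legal lists, and learns maximum-score directed
    acyclic graphs by exact dynamic programming over variable subsets, a
    greedy constructive pass, or order-based local search. Includes exact
    structure-count formulas, a pruning-level sweep that quantifies the
    accuracy/speed trade-off as a relative score discrepancy, readers and
    writers for whitespace-delimited discrete data and GOBNILP/Jaakkola
    local-score files, a synthetic-data generator (random DAGs,
    Dirichlet-sampled conditional probability tables, ancestral sampling),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
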