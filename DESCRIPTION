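Package: inpadr
Title: Protein Prioritization for Adverse Drug Reactions by Random Walk
    on an Integrated Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein targets underlying adverse drug reactions
    (ADRs) by random walk with restart on a heterogeneous network that
    joins a confidence-weighted protein-protein interaction network, an
    ADR similarity network built from Jaccard indices of drug
    co-occurrence, and a bipartite layer of known protein-ADR relations.
    Provides the block transition model with a tunable cross-layer
    jumping probability, seed construction splitting initial mass
    between a query ADR and its known proteins, leave-one-out
    cross-validation with ROC/AUC reporting, hypergeometric-enrichment
    and PPI-only random-walk baselines, and a planted-partition
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
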