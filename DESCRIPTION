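Package: hyperlouvain
Title: Degree-Corrected Hypergraph Blockmodels and Maximum-Likelihood
    Louvain Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative clustering of hypergraphs with a degree-corrected
    hypergraph stochastic blockmodel (DCHSBM). Provides the symmetric family
    of hypergraph modularity objectives derived from the model likelihood,
    all-or-nothing (AON) modularity with size-resolved resolution parameters,
    Louvain-style maximum-likelihood inference (symmetric and fast AON
    variants), exact model samplers and synthetic planted-partition
    benchmark generators, dyadic clique-projection baselines, and model
    comparison via BIC across affinity families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
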