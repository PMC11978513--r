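Package: scMapBench
Title: Benchmarking Metrics for Single-Cell Reference Integration and Query Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for evaluating how feature selection and
    integration choices affect single-cell RNA-seq reference building and
    query-to-reference mapping. Provides the data model and preprocessing for
    reference/query splits with designated unseen populations, a splat-style
    negative binomial count simulator and embedding fixtures with known
    structure, simple and supervised feature selectors, multinomial logistic
    regression label transfer, a panel of integration, mapping, classification
    and unseen-population metrics (LISI variants, batch PCR, cell-specific
    mixing score, batch-balanced NMI, isolated label scores, graph
    connectivity, local density factor differences, Mahalanobis cell and label
    distances, Milo-style neighborhood differential abundance), and
    baseline-anchored score scaling, category aggregation, overall scoring and
    ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    FNN,
    igraph,
    cluster,
    nnet,
    MASS,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
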