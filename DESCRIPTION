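Package: similearn
Title: Similarity Learning for Functional Association Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Improves a combined functional-association gene network by
    learning, per ontology category, a bilinear gene-gene similarity
    function from annotation-derived triplets with an online
    Passive-Aggressive algorithm, reconstructing the network with the
    learned similarity, and predicting gene function by graph-Laplacian
    label propagation. Includes Resnik and best-match-average semantic
    similarity over an ontology DAG, equal-weight multi-network
    integration with top-k sparsification, cross-validated per-term AUC
    evaluation, and a self-contained synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
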