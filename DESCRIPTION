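Package: nhmc
Title: Network-Aware Predictive Clustering Trees for Hierarchical
    Multi-Label Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns predictive clustering trees for hierarchical
    multi-label classification (HMC) tasks such as gene function
    prediction over FunCat- or Gene Ontology-style class hierarchies.
    The split heuristic combines hierarchy-weighted class-vector
    variance reduction with a network autocorrelation statistic (an
    HMC adaptation of Geary's C) computed over an example-linkage
    network, e.g. a protein-protein interaction network, that is used
    only during training. Includes readers and writers for a
    hierarchical-class ARFF dialect and edge-list networks, per-class
    precision-recall evaluation with averaged AUPRC, a synthetic
    benchmark generator with tunable guilt-by-association
    autocorrelation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
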