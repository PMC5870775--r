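Package: upstream
Title: Causal Reasoning on Signed Directed Networks for Upstream Regulator
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts upstream regulators of differential expression
    signatures by causal reasoning over a signed, directed interaction
    network. Parses networks in the simple interaction format (SIF), builds
    a computational causal graph in which every entity carries a positive
    and a negative copy so that path sign is encoded by reachability,
    scores every signed regulator hypothesis against a ternary signature at
    a bounded path length, attaches permutation-null and hypergeometric
    significance, filters hypotheses for robustness across increasing path
    lengths by consensus, and reconstructs Cytoscape-ready explained
    regulatory subnetworks with node annotation tables. Includes a
    synthetic-network and planted-regulator signature simulator and an
    exhaustive walk-enumeration oracle used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
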