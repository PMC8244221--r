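Package: ppiPaths
Title: Maximum-Confidence Path Search and Subnetwork Extraction on
    Protein Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Finds the most probable chain of interactions (the "strongest
    path") between two sets of proteins on a confidence-weighted
    protein-protein interaction or signaling network, by reweighting each
    edge to -(log D + log P(e)) and running a nonnegative-weight shortest
    path search between a super-source and a super-sink. Extracts the set
    of nodes lying on any epsilon-suboptimal path from forward and backward
    dual distances, greedily expands a protein set by the external nodes
    with maximal total interaction confidence, classifies hop-minimal paths
    in signed regulatory networks as activating or inhibitory by their edge
    sign product, and provides hypergeometric enrichment, FDR correction
    and precision/recall statistics for benchmarking reconstructed
    pathways. Includes synthetic network generators and brute-force oracles
    for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Pathways, NetworkEnrichment
RoxygenNote: 7.3.3
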