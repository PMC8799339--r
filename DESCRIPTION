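Package: netkey
Title: Entropy-Weighted Key-Target Discovery and Network Proximity on
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for key-target discovery on protein-protein interaction
    networks. Ranks nodes by an entropy-weighted combination of five
    centrality indicators (degree, closeness, betweenness, eccentricity,
    PageRank), ranks hubs by Maximal Clique Centrality, intersects the two
    screens into a key-target set, and scores drug-component target sets
    against the key set with a network-proximity separation score on a
    background interactome. Includes STRING-style edge-list and SIF readers,
    gene-set assembly rules, and synthetic-data generators (scale-free
    backgrounds, planted high-centrality modules, component-target maps
    with known ground truth) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
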