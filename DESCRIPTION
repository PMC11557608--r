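Package: UPRnet
Title: Statistical-Mechanics Characterization of Protein-Protein Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the topological and statistical-mechanics analysis of
    protein-protein interaction (PPI) networks such as the unfolded protein
    response (UPR) interactomes retrieved from STRING. Provides STRING-style
    edge-list ingestion, a descriptor suite (degree, closeness, betweenness,
    clustering, eccentricity, density, diameter, barycenter, modularity,
    average path length, efficiency) with size-normalized variants,
    degree-preserving configuration-model null ensembles with z-scores and a
    non-parametric statistical battery, the Generalized Hamming Distance
    between same-size networks, robustness under random and metric-targeted
    node-removal attacks with jump detection, and structural controllability
    with minimum driver-node identification via maximum matching and Kalman
    rank verification. Seeded synthetic network generators emulate the size,
    density, hub and community structure of curated UPR networks so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
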