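Package: agesocnet
Title: Age Structure and the Topology of Animal Social Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis tools for studying how adult ageing
    shapes animal social networks. Provides a kin-structured, age-stratified
    random-network generator in which edge probabilities depend on the age
    classes and kinship of each dyad; weighted and binary network metrics
    (eigenvector centrality, betweenness, closeness, clustering, and global
    degree/diameter/transitivity/density summaries); a longitudinal synthetic
    grooming-data generator with logged ground truth for parameter-recovery
    studies; and hierarchical regression models of individual network
    trajectories using within-individual age centring, together with
    group-level models of global network structure against the proportion of
    old individuals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    glmmTMB,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
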