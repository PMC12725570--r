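Package: fcnflow
Title: Fragmentation of River Networks and Temporal Change in Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking river-network fragmentation and habitat change
    to temporal change in fish community composition. Delineates functionally
    connected networks (FCNs) from dendritic reach hydrography under barrier
    scenarios, computes physical habitat richness and rarity-weighted richness
    per network, links the longest network per subwatershed (HUC-12) to
    two-period fish presence-absence data, tests per-site temporal
    beta-diversity (Sorensen decomposition) by permutation, and attributes
    community change to habitat and condition predictors with spatial random
    forests (Moran eigenvector maps). Includes a seeded generator of synthetic
    dendritic networks, barriers and fish communities with a controllable
    fragmentation-to-loss effect so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
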