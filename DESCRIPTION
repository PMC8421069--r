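Package: mvnstroke
Title: Microstroke Simulation and Topological Analysis of Cerebral
    Microvascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-based steady and red-blood-cell-resolved blood flow
    simulation in cortical microvascular networks, with a single- and
    multi-capillary occlusion (microstroke) protocol and the associated
    topological and perfusion analyses: microstroke-capillary type
    classification, thresholded relative flow change by generation,
    analysis-box perfusion deficits, arteriole-venule (AV) factor,
    topologically supplied tissue volume, and counting of flow paths
    between descending arterioles and ascending venules. Includes a
    synthetic network generator (capillary lattice plus penetrating
    arteriole and venule trees) so the full pipeline runs without
    external reconstructions.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
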