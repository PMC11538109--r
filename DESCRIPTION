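Package: mpmimage
Title: Automated Image Analysis of Microvessel Formation, Cell Coverage, and
    Invasion in Microphysiological Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-throughput analysis of multi-channel fluorescence images of
    3D cancer and endothelial cell co-culture microphysiological models.
    Computes Z-projections (focus stacking, minimum, maximum, median, mean)
    and cell coverage area from two-component Gaussian-mixture thresholding
    inside an automatically detected well boundary; classifies Z-planes to
    measure cancer invasion depth; and quantifies microvessel networks by
    vesselness filtering, discrete-Morse ridge ("Morse skeleton") graph
    extraction with persistence cancellation, and persistent-homology branch
    decomposition of the shortest-path-tree filtration. Ships a seeded
    synthetic-fixture generator (wells, invasion Z-stacks, rendered vessel
    trees) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    nnet,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
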