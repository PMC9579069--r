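Package: numgraph
Title: Graph-Theoretic and Occupancy Indices for Random Dot Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies two-dimensional dot configurations of the kind used
    as stimuli in numerosity-perception experiments. Generates random dot
    patterns inside a circular aperture by rejection sampling with a minimum
    spacing constraint, builds the random geometric graph induced by any
    connectivity distance, and computes eleven normalized indices: total
    degree, total edge length, random-walk cover time, eigenvector
    centrality, connected components, clique number, domination number,
    independence number, local and global clustering coefficients, and the
    occupancy (union-of-disks area) model. Provides the distance-sweep
    machinery built on these indices: per-index maximum-standard-deviation
    distance selection, significance-masked Pearson correlation matrices,
    and varimax-rotated principal component analysis of the resulting
    index table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
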