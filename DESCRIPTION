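Package: eigenalign
Title: Eigenvector Alignment Analysis of Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spectral comparison of weighted functional-connectivity
    networks.  Implements the eigenvector alignment (EA) statistic --
    the angle between two nodes' position vectors in the Euclidean
    space spanned by the dominant eigenvectors of a thresholded
    connectivity matrix -- together with its supporting stack:
    Cluster-Span Thresholding of weighted graphs, dominant-eigenvector
    embedding with eigenvector centrality, deterministic communities of
    dynamical influence (CDI), and Welch-test group comparisons of
    alignment, centrality, connectivity and community size, screened
    through a random-model significance filter.  Includes seeded
    synthetic-cohort generators so the whole pipeline can be exercised
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
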