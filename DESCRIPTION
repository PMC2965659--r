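Package: netcompare
Title: Comparing Networks That Differ in Size and Connectivity Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building graphs from connectivity matrices and for
    comparing networks that differ in their number of nodes and average
    degree. Implements the common thresholding regimes (fixed threshold,
    fixed average degree, fixed edge density), surrogate- and range-based
    normalization of path length and clustering (including the small-world
    index and its size bias), direct graph distances and correlations with
    attainable bounds, baseline-model comparison of graph-measure
    differences, edge-removal estimation of degree dependence, dyad/triad
    motif censuses with surrogate significance testing, and exponential
    random graph models with motif statistics fitted by Monte-Carlo maximum
    likelihood. Includes canonical network generators (ring lattice,
    Erdos-Renyi, Watts-Strogatz, Barabasi-Albert, degree-preserving
    rewiring) and a synthetic connectivity-matrix generator emulating
    sensor-level functional connectivity data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
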