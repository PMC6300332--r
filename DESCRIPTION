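Package: dynetscan
Title: Temporal Aggregation and Scan-Based Surveillance of Dynamic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how temporal aggregation and count-to-binary
    conversion affect prospective anomaly detection in dynamic social
    networks. Simulates sequences of undirected communication networks from a
    degree-corrected stochastic block model (DCSBM) with Pareto-distributed
    node propensities, injects sustained communication-rate shifts into a
    target community, monitors the sequences with Priebe's moving-window scan
    statistic (node degree and first two neighborhood sizes, two-stage
    windowed standardization), and estimates run-length properties (false
    alarm rate, detection rate, conditional signal delay) by Monte Carlo.
    Includes non-overlapping temporal aggregation of count networks,
    thresholded binarization, temporal edge-list input/output, and an
    experiment harness for grids of scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
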