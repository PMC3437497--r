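Package: scfc
Title: Structure-Function Relations in Wilson-Cowan Brain Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of Wilson-Cowan neural population
    oscillators coupled by a structural connectome, estimates functional
    connectivity from the simulated activity (Pearson correlation and mean
    phase coherence via the analytic signal), characterizes the resulting
    functional networks with graph-theoretic measures (path length,
    clustering, small-world index against an Erdos-Renyi reference), and
    quantifies structure-function agreement with the Jaccard similarity of
    binarized connectivity matrices. A weakly-coupled-oscillator phase
    reduction (limit cycle, adjoint phase response, phase interaction
    function H and its slope at zero lag) predicts the parameter regions
    where functional connectivity recovers the structural substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
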