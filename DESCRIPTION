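Package: cruspark
Title: Stochastic Lattice Simulation of Cardiac Calcium Sparks from
    Coupled RyR2 and IP3R2 Clusters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates local sarcoplasmic-reticulum calcium release events
    (calcium sparks) from a single cardiac calcium release unit on a 30-nm
    lattice. Two-state ryanodine receptor (RyR2) gating with luminal
    regulation and allosteric coupling, six-state park/drive IP3 receptor
    (IP3R2) gating, and explicit-Euler reaction-diffusion of dyadic and
    junctional-SR calcium with three cytosolic buffers are advanced together
    on a fixed time step. Includes geometry generators for checkerboard
    (control) and fragmented (heart-failure-like) receptor arrangements,
    spark detection and morphology metrics, batch experiment protocols, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
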