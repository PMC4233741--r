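Package: moranet
Title: Exact Fixation Probabilities and Fixation Times for the Moran
    Process on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evolutionary dynamics on network-structured
    populations under the birth-death Moran process with constant
    selection. Builds exact transition matrices for the mutant-invasion
    Markov chain on small undirected graphs, collapses states by graph
    automorphism orbits, and solves the absorbing chain for fixation
    probabilities, unconditional and conditional fixation times, and
    per-state conditional sojourn times via the fundamental matrix.
    Includes generators for the standard small network families (complete
    graph, ring, line, star, shovel, diamond, square lattices with
    optional periodic boundaries and diagonal links), a fast Monte Carlo
    simulator for populations too large for exact solves, and high-level
    analyses: amplifier-of-selection classification, fixation-time
    orderings under link removal, sojourn-time crossovers, and the effect
    of initial mutant placement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
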