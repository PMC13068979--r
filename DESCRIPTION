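Package: latticefold
Title: Coarse-Grained Lattice Protein Folding as Binary Optimization
Version: 0.1.0
Authors@R: person("latticefold", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Encodes coarse-grained lattice protein folding (HP or
    Miyazawa-Jernigan-style contact potentials) as higher-order and quadratic
    unconstrained binary optimization problems. Provides four model encodings
    (coordinate-based and turn-based, on the simple-cubic and the tetrahedral
    diamond lattice built from two interleaved FCC sublattices), iterated
    Rosenberg quadratization, simulated-annealing, parallel-tempering and
    exhaustive solvers, exact self-avoiding-walk oracles, and hardness and
    performance diagnostics (spin-overlap distributions, time-to-solution,
    QUBO resource metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
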