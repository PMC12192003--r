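Package: ipdrep
Title: Reputation-Based Partner Choice in the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytically solvable model of a society of agents playing the
    Prisoner's Dilemma under reputation-based partner choice. Each agent
    carries a fixed reputation q in [0,1], its probability of cooperating;
    the second player of every game is the most reputable of n uniformly
    sampled candidates, an order-statistic matching rule. The package
    evaluates exact expected-income curves I(q) by quadrature or closed
    form for six built-in reputation densities and user-supplied ones,
    locates income extrema, computes society-level mean income and its
    dispersion, and validates everything against a seeded agent-based
    Monte Carlo simulator with reporting utilities for curve, extremum,
    summary-table and analytic-vs-simulation comparison exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
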