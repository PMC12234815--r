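Package: cadyn
Title: Adaptive Dynamics of Competitive-Ability Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the zero-sum, symmetric game of microbial competition in
    which each species is a distribution of competitive ability on [0,1] (or on
    a discrete grid k/M), subject to a bound of 1/2 on its mean competitive
    ability (MCA).  Implements the payoff functionals and Nash-equilibrium
    checkers for both the vector-valued and function-valued games, the
    selection gradient of invasion fitness, the projection that enforces the
    MCA constraint, and the resulting constrained adaptive dynamics with
    abrupt Heaviside switching between the free and projected flows.  The
    vector flow is linear; the package provides its exact spectral structure
    (characteristic polynomials with binomial coefficients, parity laws for
    ranks and kernels, Jordan chains for the zero eigenvalue, and closed-form
    rotation-block propagators) alongside forward-Euler integration with
    per-step diagnostics, evolutionary-branching and low-MCA numerical
    experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    withr,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve
Config/testthat/edition: 3
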