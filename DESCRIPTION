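Package: infolength
Title: Information Geometry of Time-Dependent Stochastic Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the information geometry of time-dependent stochastic
    processes. Computes distances between probability density functions
    (Wootters, Kullback-Leibler, Jensen, squared Euclidean), the information
    rate Gamma(t) and path-dependent information length L(t) of an evolving
    density, exact propagation of (non-autonomous) Ornstein-Uhlenbeck
    processes, a conservative Chang-Cooper/Crank-Nicolson Fokker-Planck
    solver, an Euler-Maruyama Langevin simulator, a dichotomous-noise coupled
    two-component system, non-equilibrium thermodynamic functionals (entropy
    production, heat, work, free energy, relative entropy to the stationary
    state) with their Gamma-based identities and bounds, and minimum-L
    geodesics in the Gaussian statistical manifold with synthesis of the
    control protocols D(t), v(t) that realize them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
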