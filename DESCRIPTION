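Package: diffGillespie
Title: Differentiable Gillespie Simulation of Stochastic Gene Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A differentiable variant of the Gillespie stochastic simulation
    algorithm for chemical reaction networks. Discrete reaction selection and
    state updates are replaced by smooth sigmoid and Gaussian surrogates so
    that simulated trajectories, and any summary statistic computed from
    them, become differentiable functions of the kinetic parameters under
    common random numbers. The package couples the smoothed simulator to
    exact forward-mode pathwise sensitivities, enabling gradient-based
    kinetic-parameter estimation (ADAM in log-parameter space, curvature
    confidence intervals, loss landscapes) and gradient-based design of
    gene-regulatory circuits. Built-in two-state (telegraph) and four-state
    nonequilibrium promoter models ship with analytic and master-equation
    oracles, and every smoothed result can be benchmarked against the exact
    Gillespie direct method included as ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'network.R'
    'promoters.R'
    'dga.R'
    'design.R'
    'metrics.R'
    'inference.R'
    'io.R'
    'cli.R'
    'exact.R'
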