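Package: espctm
Title: Kinetic Transition Networks by Trajectory Mapping in an
    Effective-Energy Rescaled Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies metastable states in dynamical trajectories and
    builds Markov kinetic transition networks between them.  Trajectories of
    structural metrics (e.g. backbone dihedral angles, or particle
    coordinates) are expanded in a sine/cosine basis, the slow "effective
    energy" component of the recorded potential energy is extracted by FFT
    low-pass filtering and multiple linear regression against the basis
    features, and the regression coefficients rescale the feature space
    before a principal-component reduction.  Trajectory segments are then
    clustered by spectral analysis of their similarity matrix with a robust
    Perron cluster analysis (PCCA+), and a lagged Markov transition matrix,
    stationary distribution and state lifetimes are estimated from the
    discretized trajectories.  A Langevin simulator for a Brownian particle
    on a periodic three-well landscape, together with a Boltzmann quadrature
    oracle for equilibrium basin weights, is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
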