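Package: feastfamine
Title: Kinetic Modelling of Yeast Carbon-Storage Metabolism under
    Feast/Famine Substrate Cycles
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates central carbon metabolism of Saccharomyces cerevisiae
    (glycolysis, glycerol branch, a compartmentalized trehalose cycle and
    phenomenological glycogen turnover) under repeated substrate perturbation
    (feast/famine) regimes. Implements the three-stage protocol emulation
    (chemostat steady state, block-wise feed cycles with broth-volume
    dynamics, 13C-enrichment run), carbon-13 enrichment mass balances with
    forward/backward flux splitting, glucose-sensing hexose-transporter
    kinetics with a minimum-glucose threshold, a two-step parameter
    estimation pipeline (combinatorial enzyme-subset screening followed by
    L1-regularized re-estimation), parameter-perturbation ensembles, a
    passive-transport feasibility scan, and a synthetic-data generator for
    download-free testing and parameter-recovery experiments. Ships its own
    Rosenbrock stiff ODE integrator and Levenberg-Marquardt least-squares
    optimizer implemented in C++/R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
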