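Package: netctl
Title: Network Control Theory Analysis of Brain-State Transitions
Version: 0.1.0
Authors@R:
    person("netctl", "maintainers", email = "netctl@example.org", role = c("aut", "cre"))
Description: Optimal control analysis of working-memory brain-state
    transitions on structural connectomes. Computes finite-horizon
    optimal control energy, state stability, and per-node control
    impact for linear dynamical systems defined on weighted structural
    brain networks; quantifies suboptimal-trajectory variability by
    perturbing the optimal control input of the discretized system and
    summarising the trajectory cloud with per-timestep principal
    component analysis; provides a synthetic cohort generator
    (modular FA-weighted connectomes, paired task activation states,
    group and gene-score covariates) and the covariate-adjusted
    repeated-measures statistics used for cohort inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
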