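Package: mhemuscle
Title: Real-Time Dynamically Consistent Muscle-Force Estimation by Moving
    Horizon EMG-Marker Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moving horizon estimation (MHE) of muscle forces and joint
    kinematics on Hill-type-muscle-actuated arm models, fusing electromyographic
    (EMG) envelopes and skin-marker trajectories. Implements a differentiable
    musculoskeletal core (polyline muscle geometry, rigid-tendon Hill force
    generation, first-order activation dynamics, recursive Newton-Euler
    rigid-body dynamics), a condensed Gauss-Newton solver for the per-window
    tracking problem with warm starting and initial-state chaining, a
    synthetic-data pipeline (cyclic reference motions with controlled
    co-contraction, Fourier-domain EMG noise, marker placement noise on a
    surrogate model), and an evaluation campaign (window-size sweeps, fully
    crossed noise grids, RMSE scoring, ANOVA with Bonferroni post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
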