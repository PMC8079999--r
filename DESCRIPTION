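Package: ternflow
Title: Surface-Flow Velocimetry, Seabird Tracking and Covariate-Driven
    Hidden Markov Models for Overhead Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how surface-foraging seabirds
    respond to coherent turbulence features seen from a hovering drone. Provides
    a ground-truthed synthetic data generator (vortex-street surface flow with
    erupting upwelling boils, behaviour-switching tern trajectories, rendered
    video frames), particle image velocimetry with sub-pixel cross-correlation
    and spatio-temporal median filtering, vorticity and divergence extraction,
    frame-differencing detection with Kalman multi-target tracking,
    spline-window kinematics (speed and log-tortuosity), space-time
    interpolation of flow covariates at configurable time-to-contact delays,
    and a two-state hidden Markov model with gamma state-dependent
    distributions and logit-linear covariate-dependent transition
    probabilities, including Viterbi decoding, stationary-probability curves,
    AIC model comparison and delay grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
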