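Package: adbsddm
Title: Closed-Loop Beta-Triggered Stimulation Simulation and Hierarchical
    Drift-Diffusion Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates closed-loop (adaptive) deep-brain stimulation triggered
    by subthalamic beta-band amplitude and analyses its effect on perceptual
    decision making.  Provides a synthetic-cohort generator with known ground
    truth (behaviour from a drift-diffusion process, beta-envelope series with
    task-locked modulations, stimulation traces from the controller), a Wiener
    first-passage-time likelihood with adaptive series expansions, hierarchical
    Bayesian drift-diffusion regression models with trial-wise neural and
    stimulation regressors fitted by MCMC, sliding-window stimulation-effect
    contrasts with cluster-based permutation correction, Morlet wavelet
    beta-power metrics, and nonparametric cohort statistics including a
    signed-rank power calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    readr,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
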