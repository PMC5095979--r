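Package: effconn
Title: Effective Connectivity from fMRI via Blind Deconvolution and
    Time-Varying Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating condition-specific directed (effective)
    connectivity between brain regions from fMRI time series. BOLD signals
    are extracted from peak-centred regions of interest, blind-deconvolved
    to latent neural signals with a square-root cubature Kalman filter over
    a balloon-type hemodynamic state-space model, and modelled with a
    first-order dynamic multivariate autoregressive (dMVAR) model whose
    coefficients vary over time. Coefficients are aggregated into
    condition-specific path-weight distributions, compared between groups
    edge-by-edge with false-discovery-rate control, and summarised into
    driver/hub reports. A synthetic-data module simulates an advice-taking
    luggage-screening task (trial schedules, agent-conditioned accept/reject
    behaviour) and ground-truth directed neural networks observed through a
    hemodynamic forward model, so every pipeline stage is testable by
    parameter recovery. Behavioural summaries (advice utilization, accuracy,
    monetary deductions) and the matching one-way, mixed repeated-measures
    ANOVA and t-test statistics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
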