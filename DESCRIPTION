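Package: ticfractal
Title: Fractal-Dimension Severity Scoring of Tic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the burstiness of tic event time series through the
    fractal dimension of a tic-modulated random walk. Tic onset times recorded
    in fixed-duration observation sessions are mapped to a velocity-reversal
    walker; the orientation-averaged spectral density of the trajectory is
    fitted in log-log space and the slope converted to a fractal dimension
    D_f, calibrated so that ballistic motion (no tics) scores about 2 and
    Brownian motion (maximally chaotic ticcing) scores about 1. Includes a
    bursty hierarchical point-process simulator for synthetic tic trains and
    cohorts with latent severity, a two-rater observation-noise model, and
    group-level statistics (severity-change correlation, suppression-condition
    contrasts via repeated-measures ANOVA, inter-rater agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
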