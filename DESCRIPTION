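Package: sinostrip
Title: Multiscale Collaborative Filtering of Streak Noise in Tomographic Sinograms
Version: 0.1.0
Authors@R: person("Sinostrip", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes angular streak noise from tomographic sinograms (and hence
    ring artifacts from reconstructions) by modeling streaks as stationary,
    spatially correlated noise and attenuating them with a two-stage
    collaborative transform-domain filter applied across multiple horizontal
    scales. Includes bright-/dark-field normalization, log transformation,
    detection and repair of extreme streaks from defective detector pixels,
    robust self-calibration of the streak noise level via a detail filter and
    the median absolute deviation, an iterative spline debinning scale pyramid,
    and a Shepp-Logan phantom simulator with an SNR benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
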