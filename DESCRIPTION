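Package: outbreaklaw
Title: Heavy-Tailed Outbreak-Size Distributions and Surveillance Underdetection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits discrete heavy-tailed distributions (power law, log-normal,
    exponential) to outbreak size-frequency data with Clauset-style minimum
    threshold selection by Kolmogorov-Smirnov minimization, semi-parametric
    bootstrap goodness-of-fit testing, and case-resampling bootstrap credible
    intervals. Extrapolates the fitted power law below the threshold to
    estimate the deficit of small (<10 cases) and large (>100 cases)
    outbreaks and associated illnesses relative to expectation, annualized
    and stratified by surveillance era. Includes a synthetic surveillance
    simulator with a size-dependent detection model for validation with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
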