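Package: immunodesign
Title: Optimal Blood-Sampling Schedules for Immunization Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans blood-sampling schedules for immunization studies whose goal
    is to characterize antibody kinetics. The mean antibody concentration is
    modelled by the density of a beta distribution (rescaled to study time and
    optionally shifted to allow pre-existing antibodies) until it reaches a
    plateau, so that the whole curve is pinned down by five quantities a
    clinician can state directly: the starting concentration, the time and
    height of the peak, and the time and height of the plateau. Curve
    parameters are calibrated by solving the implied nonlinear system, and
    D-optimal sampling times are found by minimizing -ln(det(FIM)+1) with a
    bound-constrained Hooke-Jeeves pattern search, where the Fisher information
    matrix assumes multivariate-normal measurements with AR(1) correlation.
    Includes D-efficiency comparison of schedules, a 12-scenario preset library,
    single- and double-parameter misspecification sweeps for robustness
    analysis, and a synthetic-measurement generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
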