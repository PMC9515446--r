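Package: coopergait
Title: Augmented Cooper Test Analysis from Wearable GNSS and Foot-IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the 12-minute Cooper run test recorded with a
    chest-worn GNSS receiver and foot-worn inertial measurement units.
    Estimates the covered distance by five methods (ground-speed strapdown
    integration, Haversine coordinate summation, latitude-peak lap counting,
    and two lap-counting hybrids) and compares them with Bland-Altman
    statistics; extracts per-gait-cycle temporal parameters, duty factor,
    spring-mass vertical stiffness and left/right symmetry indices; builds a
    175-metric biomechanical feature grid over five time segments; selects
    performance-relevant metrics with leave-one-out cross-validated LASSO
    (one-standard-error rule) and Welch group testing; and predicts maximal
    aerobic speed and the speed at the second ventilatory threshold from the
    covered distance. A synthetic-data module emulates cohorts, oval-track
    trajectories and fatigue-drifting gait streams so the whole pipeline runs
    and is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    geosphere,
    pracma,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
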