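Package: pdscribe
Title: Handwriting and Forearm sEMG Biomarkers for Parkinson's Disease Detection and Rating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for pen-tablet
    handwriting recordings paired with 8-channel forearm surface-EMG.
    Computes muscle-activity features (per-channel RMS, tolerance-gated
    zero-crossing rates), pen-tip kinematics (velocity, acceleration and
    jerk chains with pressure and tilt summaries), micrographia descriptors
    (regression-line angle between upper and lower letter peaks) and a
    spiral precision index; selects representative features with a
    Gini-impurity decision tree; and classifies healthy vs Parkinson's
    Disease and mild vs moderate patients with a feed-forward neural
    network whose topology is optimized by a multi-objective genetic
    algorithm. A seeded synthetic-cohort generator reproduces the assumed
    pathological signatures (micrographia, tremor, bradykinesia, altered
    pen pressure and muscle activity) so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    signal,
    withr,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
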