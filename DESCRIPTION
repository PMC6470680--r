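Package: racewalkr
Title: Automatic Detection of Race-Walking Faults from Inertial Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for automatic detection of the two
    race-walking faults (loss of contact and knee bent) from lower-limb inertial
    measurement units. Provides a synthetic cohort generator emulating a
    multi-lap testing protocol, zero-phase Butterworth filtering, coach-channel
    transition detection, shank-gyroscope stride segmentation with time
    normalization, per-stride feature extraction (time-domain statistics and
    autocorrelation peaks), a bank of nine classifiers (decision tree, linear /
    quadratic / cubic support vector machines, four k-nearest-neighbour
    variants, and a three-hidden-layer neural network) evaluated by two-fold
    session cross-validation, and a cascaded selection funnel on accuracy,
    recall and precision with a ROC-distance goodness index for the collapsed
    regular-vs-irregular model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    e1071,
    rpart,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
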