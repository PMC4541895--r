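Package: insolegait
Title: Fuzzy Gait-Phase Detection and Foot-Movement Recognition from
    Sensorized Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ambulatory gait monitoring with pressure-sensing
    insoles sampled at 50 Hz. Implements a fuzzy rule-based gait phase
    detection algorithm (GPDA) that demarcates the loading response,
    mid-stance, terminal stance, pre-swing and swing phases from four
    force-sensitive resistors per foot, with two-stage quartile
    calibration and sigmoid membership functions combined by the minimum
    T-norm. A companion activity-recognition pipeline extracts 37
    time- and frequency-domain features from 128-sample ring buffers,
    reduces them with scatter-matrix principal component analysis, and
    discriminates walking forward from seven other foot-movement
    patterns with a Gaussian naive Bayes classifier. Includes a
    synthetic insole-signal simulator for all eight movement patterns,
    six-fold cross-validation utilities, phase-duration comparison
    against the canonical gait-cycle partition, and a command-line
    interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
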