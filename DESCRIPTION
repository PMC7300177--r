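Package: runexp
Title: Classification of Running Experience from Foot-Ankle Stance
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for discriminating long-distance runners'
    experience level from foot-ankle stance-phase mechanics. Training
    history is scored with a two-stage Mamdani fuzzy decision-support
    system; raw ground reaction forces and multi-segment foot kinematics
    are low-pass filtered, segmented into stances by a vertical-force
    threshold, time-normalized to 101 points and averaged over 10 steps;
    nine body-weight-normalized discrete ground reaction force variables
    are extracted; waveforms are assembled into a subjects-by-1010 matrix
    and decomposed by principal component analysis; and one-vs-all linear
    support vector machines with sequential forward feature selection
    driven by the cross-validated Matthews correlation coefficient
    classify the experience groups. Includes a synthetic cohort generator
    with planted group effects so the full pipeline is testable without
    motion-capture data, a critical-binomial minimum significant accuracy,
    and effect-size based interpretation of the selected components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
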