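Package: saccurv
Title: Saccade Trajectory Curvature Analysis for Double-Step Saccade Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze saccade trajectory curvature in double-step saccade
    experiments with visual, auditory and audiovisual distractors. Provides a
    seeded synthetic-data generator emulating 1 kHz gaze recordings of two-saccade
    sequences with injectable distractor-evoked curvature and artifacts,
    velocity-threshold saccade detection, trial selection and distractor-interval
    classification, trajectory rotation/resampling/normalization and the
    median-angular-deviation curvature statistic, and hierarchical
    (within-participant) bootstrap inference, tied together in a reproducible
    pipeline with delimited-text readers and writers and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
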