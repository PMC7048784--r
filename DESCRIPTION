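Package: sitpipe
Title: Automated Behavioral Biomarkers from Simulated Social Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for the Simulated Interaction Task
    (SIT), a standardized video-dialog paradigm for quantifying non-verbal
    social behavior. Reads per-frame facial tracking tables in the OpenFace
    output dialect, applies frame- and participant-level quality control,
    slices recordings into conversation segments, and computes behavioral
    biomarkers: action-unit occurrence and intensity, social smiling,
    time-shifted windowed facial mimicry, gaze kinematics, and Praat-style
    prosodic voice features (F0, jitter, shimmer, harmonics-to-noise ratio,
    MFCCs). Builds per-subject secondary feature matrices, runs
    non-parametric group statistics with effect sizes, and evaluates a
    random-forest diagnostic classifier under leave-one-out cross-validation
    with nested hyperparameter selection. Includes a seeded synthetic-cohort
    generator (facial tracks, gaze series, voiced audio) so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ranger,
    car,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
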