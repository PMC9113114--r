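Package: cerebmotor
Title: Cerebellar Volumetrics and Sensorimotor Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scoring and statistical pipeline for studies of cerebellar
    structure and sensorimotor behavior. Implements precision-grip force
    variability scoring (zero-phase Butterworth filtering, rise-offset
    detection, sustained-phase extraction, coefficient of variation),
    visually guided saccade scoring (velocity-threshold saccade detection,
    primary-saccade selection, anticipatory exclusion, per-condition error
    variability), ingestion of cerebellar lobule volume tables from
    automated segmentation tools, and linear mixed-effects brain-behavior
    association models with iterative interaction pruning,
    Benjamini-Hochberg false-discovery-rate control, and simple-slopes
    probing of interactions. A calibrated synthetic-data generator emulates
    cohorts, region-of-interest volume tables, clinical scores, force
    traces, and gaze traces with known ground truth so that every stage of
    the pipeline can be exercised and validated without access to human
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
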