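Package: fallwatch
Title: Threshold-Based Fall Detection from Waist-Worn Triaxial Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for fall detection with a waist-worn triaxial
    accelerometer sampled at 200 Hz: reading and writing plain-text trial
    recordings with raw ADC counts, conversion to g, causal Butterworth
    low-pass preprocessing, fourteen classical time-domain features (sum
    vector magnitude, peak-to-peak amplitude, trunk orientation, jerk,
    sliding-window standard deviation magnitude, signal magnitude area and
    approximate velocity) over full-overlap sliding windows, trial-level
    threshold classification with maximum-accuracy (T1) and
    maximum-sensitivity (T2) threshold policies, sensitivity, specificity
    and accuracy metrics, and class-stratified k-fold cross-validation.
    Includes a seeded synthetic trial generator emulating gait, sit and
    jump activities of daily living, falls with a free-fall-plus-impact
    critical phase, and an elderly cohort with reduced movement
    amplitudes, so the whole pipeline can be exercised and validated
    without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
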