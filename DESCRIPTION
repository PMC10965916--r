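Package: wearmood
Title: Mood-Disorder Symptom Scoring from Wristband Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores all 17 Hamilton Depression Rating Scale (HDRS) and 11
    Young Mania Rating Scale (YMRS) symptom items from multivariate
    Empatica E4-style wristband recordings (tri-axial acceleration, blood
    volume pulse, electrodermal activity, heart rate, skin temperature).
    Provides quality control and non-overlapping window segmentation of
    raw sensor streams, a multi-task ordinal classifier with an
    adversarial subject critic encouraging subject-invariant
    representations, imbalance-aware training (focal loss, probability
    thresholding, severity-bin resampling with loss re-weighting), a
    quadratic weighted Cohen's kappa training loss, and a full evaluation
    suite: per-item quadratic kappa and macro F1, temporal drift curves,
    residual partial-correlation networks via a graphical lasso with EBIC
    selection, per-subject performance screens, total-score RMSE, and
    leave-one-channel-out ablations. A deterministic synthetic cohort
    generator emulating the E4 export dialect makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
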