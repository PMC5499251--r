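Package: beatnet
Title: Patient-Specific ECG Heartbeat Classification from Time-Frequency Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for AAMI-style heartbeat classification of single-lead ECG.
    Implements a signal-adaptive frequency slice wavelet transform that images
    each beat in the time-frequency plane, tied-weight denoising auto-encoders
    with greedy layer-wise pretraining for unsupervised feature abstraction, a
    softmax deep neural network classifier, and the three-stage training
    workflow (unsupervised pretraining, interpatient fine-tuning, and
    patient-specific adaptation on an initial annotated portion of a record).
    Includes baseline-wander removal, derivative-based QRS detection,
    fixed-window beat segmentation, AAMI class mapping and record splits for
    the MIT-BIH arrhythmia database, evaluation metrics (per-class
    sensitivity, specificity, positive predictive value, accuracy and
    geometric means), and a synthetic annotated ECG generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
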