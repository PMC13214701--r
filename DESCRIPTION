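Package: gliomaOCT
Title: Intraoperative OCT Glioma Detection: Parametric Maps, Blockwise SVM
    Segmentation and Human-in-the-Loop Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for intraoperative optical coherence
    tomography (OCT) of brain tissue. Computes depth-resolved optical
    attenuation coefficient (OAC) and refined speckle contrast (RSC)
    parametric maps from B-scans with signal-to-noise masking, extracts
    blockwise two-feature vectors, trains a standardized linear
    one-vs-rest support vector machine to segment normal white matter,
    damaged white matter and tumor, applies a deterministic contextual
    rule filter that models the human-in-the-loop override of implausible
    scattered positives, and evaluates multi-reader forced-choice
    diagnostic performance with confusion-matrix metrics, inter-rater
    consistency and scan-level percentile bootstrap confidence intervals.
    Includes a seed-deterministic synthetic B-scan and reader-panel
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    e1071,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
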