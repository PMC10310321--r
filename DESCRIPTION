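Package: vvsreadout
Title: Linear Readouts of a Ventral-Visual-Stream Proxy Versus Primate Choice Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a linear readout of a ventral visual
    stream (VVS) proxy is sufficient to account for primate visual
    discrimination behavior. The package generates synthetic morph-continuum
    stimuli and simulated observers with known ground truth, extracts
    layer-indexed features from a pluggable image encoder (a seeded
    random-weight convolutional network or flattened pixels), fits
    cross-validated ridge maps from encoder layers to simulated electrode
    responses with split-half noise correction, trains L2-regularized
    logistic category readouts under random and morph-sequence-holdout
    splits, estimates odd-one-out task performance with a leave-one-out
    pseudo-experiment protocol, and quantifies within- and between-subject
    split-half reliability, model-behavior fits, and empirical percentile
    ("subject-like") statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    png,
    jsonlite,
    yaml,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
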