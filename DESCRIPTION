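Package: rpafnet
Title: Atrial Fibrillation Detection from Recurrence-Plot Images of ECG Leads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects atrial fibrillation (AF) versus normal sinus rhythm from
    multi-lead ECG by rendering delay-embedded recurrence plots of individual
    leads and classifying them with a shallow three-stream convolutional
    network that uses factorized 1x7/7x1 asymmetric convolutions (depth 12,
    SiLU activations). Includes a seeded synthetic multi-lead ECG generator
    (Gaussian P-QRS-T morphology, log-normal RR intervals, fibrillatory
    f-waves dominant on a V1-analog channel), signal preparation (resampling,
    segmentation, z-score normalization, balanced record-disjoint splits),
    forward stepwise search for a minimal informative lead subset with
    fivefold cross-validation and Welch t-tests, confusion-matrix metrics,
    and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    withr,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
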