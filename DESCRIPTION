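Package: sonomil
Title: Attention-Based Multiple Instance Learning for Patient-Level
    Ultrasound Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Weakly supervised risk classification of patients from
    variable-length sets ("bags") of grayscale ultrasound-like images.
    Implements a convolutional instance encoder, tanh-scored attention
    aggregation with softmax-normalized instance weights, bag-level
    sigmoid classification, max/mean pooling ablations, Grad-CAM
    saliency maps, and an evaluation protocol with bootstrap confidence
    intervals, paired t-tests and Cohen's d. Ships a procedural
    simulator that generates image bags under the standard
    multiple-instance assumption so the full pipeline is testable
    without clinical data. The network forward and backward passes are
    implemented directly on BLAS matrix products, so no external deep
    learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
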