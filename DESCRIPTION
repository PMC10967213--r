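Package: survmixr
Title: Pathway-Image ConvMixer Models for Overall-Survival Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structuralizes pathway-level gene expression into 2D patch-grid
    images, trains a compact ConvMixer-style convolutional network to classify
    short-, mid- or long-term overall survival, and interprets the trained
    model through Grad-CAM activation maps, per-pathway Wilcoxon rank-sum
    tests with Bonferroni correction, rank-based single-sample pathway
    scoring, and Kaplan-Meier / log-rank survival comparison. Includes a
    synthetic-data generator with known pathway-level signal so every stage
    of the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
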