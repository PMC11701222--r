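Package: ipghsi
Title: Iterative Pseudo-Label Generation for Semi-Supervised
    Hyperspectral Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised classification of hyperspectral scenes from a
    handful of labelled pixels per class. The cube is decomposed into
    overlapping three-band groups, each group is segmented by a promptable
    segmenter seeded with point prompts, per-group masks are fused by
    spectral majority voting, and high-confidence pseudo-labels are selected
    through cosine-similarity confidence and uncertainty gates, then fed
    back as new prompts over a fixed number of iterations. The augmented
    label set trains a patch-based 2D convolutional network. Includes a
    synthetic-scene generator with known class regions and spectral
    signatures, an oracle segmenter backend with controllable noise for
    fully reproducible experiments, and confusion-matrix metrics (overall
    accuracy, average accuracy, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
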