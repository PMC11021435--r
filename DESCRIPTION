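Package: lesionbench
Title: Robustness, Consistency and Shape-Texture Bias Analysis for Medical Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testbed for probing what image classifiers rely on when they read
    medical images. Provides a synthetic lesion-image generator with known
    class-coding structure (boundary shape, interior texture, or lesion
    location), a registry of sixteen image corruptions at five severities,
    random-translation pairs under a bounded image-loss budget, bounding-box
    occlusion, and a shape/texture cue decomposition; multi-label AUROC and
    confusion metrics with fold-wise confidence intervals, a translation
    consistency statistic, AUROC degradation summaries, and radial Fourier
    amplitude profiles of images and of model input gradients; two tiny
    CPU-trainable reference classifiers (local convolution with pooling, and
    patch embedding with global self-attention) behind a uniform
    train/predict contract; a per-class weighted two-model ensemble; and
    experiment drivers that tie these together into reproducible report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
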