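Package: mammofuse
Title: Dual-Stream Convolutional-Transformer Fusion for Mammography Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale, fully testable implementation of a hybrid
    mammography classifier that pairs a local texture encoder (7x7 depthwise
    convolutions in inverted-bottleneck blocks with layer normalization) with
    a global shifted-window attention encoder (scaled cosine attention,
    learnable temperature, relative position bias), fuses the two streams by
    bi-directional multi-head cross-attention, and classifies the fused
    representation with a prototype-anchored similarity head using a
    Student-t kernel. Includes CLAHE/min-max preprocessing, online
    augmentation (geometric policy, RandAugment-style operations, MixUp),
    Grad-CAM saliency, patient-level stratified splitting and five-fold
    cross-validation with percentile bootstrap confidence intervals, an
    AdamW training engine with cosine-annealed learning rate and EMA, an
    ablation harness, and seeded generators for synthetic mammogram-like
    cohorts so everything runs on one CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
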