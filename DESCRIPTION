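Package: cytoxai
Title: Interpretable Blood-Smear Cell Classification with Hybrid
    CNN-Transformer Features and Adaptive Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully seeded framework for leukemia blood-smear
    image classification and post hoc explanation. Provides a synthetic
    smear generator with class-dependent cell morphology and ground-truth
    nucleus masks; class-aware augmentation balancing with manifest-based
    dataset I/O; a hybrid classifier combining a convolutional encoder with
    channel-wise morphological attention, a vision transformer with
    token-wise conceptual attention, and a bounded (tanh) fusion layer; a
    controller head that weights four attribution methods (Grad-CAM, SHAP,
    Integrated Gradients, LIME) per input; reference implementations of
    the four attribution methods with explanation-quality metrics; and a
    training and evaluation harness with fixed splits, stratified k-fold
    cross-validation, three optimizers and an ablation grid. The network
    and its backpropagation are implemented in base R matrix code, so
    every stage is testable on one CPU without external model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
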