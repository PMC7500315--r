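Package: fastbcnn
Title: Bilinear and Fast Bilinear Pooling Networks for Fine-Grained
    Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-grained classification of histopathology-style images with
    bilinear convolutional networks. Implements two-stream and fast
    (single-stream) bilinear pooling of convolutional feature maps, the
    signed-square-root and L2 normalization chain, squeeze-and-excitation
    channel attention, a small trainable convolutional backbone with manual
    backpropagation, stratified k-fold cross-validation with oversampling for
    BreaKHis-style image trees, ROC/AUC and t-SNE evaluation utilities,
    Grad-CAM localization heatmaps, and a seeded synthetic texture-image
    generator for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
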