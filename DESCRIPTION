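Package: fbanet
Title: Feature-Enhanced Bi-Level Attention Networks for Sketch Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a feature-enhanced bi-level attention network for
    classifying raster sketches, aimed at automated screening of
    House-Tree-Person (HTP) drawings for signs of depression. Sparse stroke
    features are enhanced by averaging convolutional stem features over
    overlapping local patches and fusing them with global-image features; a
    bi-level attention block combines a multi-head self-attention stack over
    spatial tokens with a three-branch cross-dimension (triplet) attention,
    compensated by the global feature map, before a convolutional
    classification head. The package provides the full transfer-learning
    protocol (supervised pre-training on a many-class sketch corpus,
    fine-tuning under stratified k-fold cross-validation with a warmup-cosine
    SGD schedule), confusion-matrix metrics with fold aggregation, Grad-CAM
    saliency maps, synthetic sketch generators emulating both corpora, and a
    command-line interface. All network forward and backward passes are
    implemented in base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
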