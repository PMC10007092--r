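Package: sswan
Title: Wavelet-Domain Attention Networks for 2D Brain-Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements SSW-AN, a self-supervised wavelet-based attention
    network for semantic segmentation of 2D MRI brain-tumor slices.  The
    network operates on the four single-level discrete wavelet coefficient
    channels of a bicubic baseline image, passes them through stacked
    attention blocks combining channel attention (shared-MLP gating of
    globally pooled statistics) and spatial attention (7x7 convolution of
    channel-pooled maps), and learns the wavelet coefficients of the
    residual between the target image and the bicubic baseline, alongside
    a softmax segmentation head.  Includes a pure-R training engine with
    hand-derived gradients and Adam, Dice loss variants, a segmentation
    metric suite, a synthetic BraTS-like phantom generator with nested
    tumor sub-regions, NIfTI/PNG readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    png,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
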