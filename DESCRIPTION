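Package: surgiview
Title: Automated Display-Parameter Estimation for Surgical Microscope Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating the eight display-control parameters
    (brightness, saturation, contrast, cyan, gamma, magenta, hue, yellow)
    that optimize a surgical-microscope frame for cataract surgery on a
    heads-up display.  Implements the full two-stage framework: threshold
    based segmentation of the illuminated surgical field, a conditional
    image-to-image (Pix2Pix style) generator that synthesizes a
    pseudo-optimal image, a dual residual-network feature ensemble with a
    linear regression head that predicts the normalized parameters, a
    deterministic parameter renderer, full-reference image quality metrics
    (NRMSE, PSNR, SSIM) with brightness/contrast/sharpness comparisons, a
    grouped cross-validation pipeline, and a seeded synthetic ocular-scene
    generator with known ground-truth parameters for desk-scale training
    and testing.  All neural components are self-contained (im2col
    convolutions with analytic gradients); no external deep-learning
    framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
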