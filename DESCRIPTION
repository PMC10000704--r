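Package: mwisar
Title: Radar-Based Microwave Breast Imaging with Neural Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monostatic circular synthetic aperture radar (CSAR) forward
    simulation of breast tumor scenarios, rasterized ground-truth phantom
    images, and neural reconstruction of microwave images from backscattered
    electric field matrices. Implements four reconstruction architectures
    (a real-valued deep neural network, a real-valued convolutional network,
    a CNN+U-Net hybrid, and a fully complex-valued CNN+U-Net trained with a
    complex average cross-entropy loss) on a self-contained neural-network
    engine, together with an image-quality evaluation suite (MSE, PSNR, UQI,
    global SSIM, pixel accuracy) and a training/cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    yaml,
    optparse
Config/testthat/edition: 3
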