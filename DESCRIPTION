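Package: mrisynth
Title: Intramodality Brain MR Contrast Synthesis with a 2D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-to-image translation across brain MRI contrasts (T1, T2,
    FLAIR) with a 2D encoder-decoder convolutional network with skip
    connections. Provides a seeded multicontrast brain phantom simulator,
    volume preprocessing (null-slice removal, z-score intensity
    standardisation with [0,1] rescaling, bicubic slice resizing), a
    framework-independent layer-graph description of the network with
    analytic parameter counting, a CPU training harness (Adam, mean squared
    error loss, early stopping with best-checkpoint selection),
    slice-by-slice volume synthesis, and image-quality evaluation (MAE, MSE,
    PSNR, SSIM) with difference and SSIM maps and mean +/- SD report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
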