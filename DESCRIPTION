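Package: eatomo
Title: Electroacoustic Tomography Simulation, Reconstruction and Learned
    Limited-Angle Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end workflow for linear-array electroacoustic tomography
    (EAT) of nanosecond pulsed electric field (nsPEF) energy deposition.
    Simulates two-electrode energy-deposition phantoms and 128-channel
    linear-array channel data with a matched linear forward/adjoint
    operator, reconstructs single-view images by delay-and-sum
    back-projection and full-view ground truth by rotating and averaging
    views, trains a modified U-Net with a structural-dissimilarity loss to
    correct the limited-angle distortions, and evaluates image pairs with
    RMSE, PSNR, SSIM and iso-pressure DICE coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
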