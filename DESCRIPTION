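Package: veus
Title: Virtual Strain Elastography Synthesis and Quantification for Breast Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Synthesizes virtual strain elastography (V-EUS) images from B-mode
    breast ultrasound (BUS) with a conditional adversarial image translator
    (U-Net generator, global and tumor-region patch discriminators, and a
    color-rebalanced L1 loss in Lab space), built on a self-contained neural
    network engine. Includes the full quantification stack around the model:
    a 256-level blue-to-red pseudo-color codec with nearest-color decoding,
    strain-ratio computation against a 25x25-pixel reference region, global
    SSIM, strain-ratio MAPE and hue-saturation histogram correlation, ROC/AUC
    with DeLong confidence intervals and paired tests, Tsukuba-BI-RADS score
    fusion, blind-evaluation perceptual scoring, and depth-stratified
    diagnostic evaluation. A seeded speckle-phantom generator produces paired
    BUS/EUS cases with known stiffness ground truth, including depth-dependent
    attenuation artifacts, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
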