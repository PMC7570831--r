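Package: peachsae
Title: Soluble Solids Estimation from Hyperspectral Images with Stacked
    Autoencoders and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive estimation of fruit soluble solids content (SSC,
    degrees Brix) from near-infrared hyperspectral imagery. Provides white/dark
    reflectance calibration and ENVI-style cube I/O, extraction of spectral
    (ROI mean spectrum), image (band-window grayscale patch) and fused feature
    vectors, tied-weight stacked autoencoders with greedy layer-wise
    pretraining and supervised fine-tuning for deep-feature extraction, random
    forest regression of SSC on the deep features with R-squared/RMSE
    evaluation, pixel-wise SSC pseudo-color maps, and a synthetic
    hyperspectral peach-phantom generator so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    png,
    randomForest,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
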