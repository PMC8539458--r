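Package: particleaug
Title: Artifact-Overlay Data Augmentation for Nanoparticle Sensor Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for making particle segmentation networks robust against
    imaging artifacts by modifying only their training data. Provides a
    simulator for preprocessed surface-plasmon-resonance (PAMONO-like) image
    streams with an additive particle/background/artifact signal model,
    procedural generation of fading sine-wave artifacts, construction of
    full-frame artifact overlays from tiles (real reference-image cutouts or
    externally generated patches), particle-size-based rescaling augmentation,
    a compact fully convolutional U-Net segmentation network trained with the
    dice loss, Difference-of-Gaussians blob detection with frame-to-frame
    trace linking, and trace-level evaluation (object F1, count exactness,
    false positives per image) with grouped reporting across artifact regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
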