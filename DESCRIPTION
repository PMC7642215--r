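Package: staincycle
Title: Conditional CycleGAN Stain Translation from HE to Ki-67 with Weakly
    Supervised Patch Classification and Positivity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for virtual immunohistochemistry staining of histology
    images. Trains tumor/normal patch classifiers from weak bag-level labels
    by iterative top-instance multiple-instance learning, translates
    hematoxylin-eosin (HE) images into synthetic Ki-67 images with a
    class-conditioned CycleGAN (label channel concatenated to the generator
    input), and quantifies the Ki-67 positivity ratio (positive cells over
    all cells) by colour-rule nucleus detection. Includes a synthetic
    two-domain slide generator with full ground truth so the whole pipeline
    is testable end to end, plus Otsu foreground extraction and two-scale
    patch tiling. Neural-network layers (convolution, transposed
    convolution, instance normalisation) and the Adam optimiser are
    implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
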