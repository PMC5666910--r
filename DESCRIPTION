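Package: segpower
Title: Power and Sample Size for Image Segmentation Accuracy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Study-design tools for paired comparisons of two image
    segmentation algorithms against a common reference standard. Computes
    statistical power and sample sizes for paired t-test analyses of
    voxel-wise accuracy differences, using either moment-based variance
    inputs or a Dirichlet-prior model of inter-image variability summarised
    by a design factor. Corrects the minimum detectable accuracy difference
    when a lower-quality reference standard is substituted for a high-quality
    one, estimates all model parameters from pilot segmentations (including a
    conservative variance bound via a calibrated double bootstrap and a
    Dirichlet-multinomial precision estimator), and validates the formulae
    with a built-in Monte Carlo simulator of spatially correlated voxel-wise
    accuracy differences based on a Gaussian copula. Reads binary
    segmentation masks from NIfTI or MetaImage volumes or from per-voxel
    label tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
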