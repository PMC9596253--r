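Package: ctcascade
Title: Cascaded Localization and Shallow U-Net Segmentation of Small
    Tumors in CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage ("detect then segment") pipeline for small,
    irregularly shaped tumors in computed-tomography volumes. A slice-level
    localization stage finds tumor-bearing axial slices with an anchor-free
    grid detector (or a ground-truth oracle) and coarse-segments them by
    margin-expanded cropping; a shallow encoder-decoder network with an
    embedded feature-pyramid module then finely segments each crop. Includes
    Hounsfield windowing and NIfTI slice extraction, a synthetic CT phantom
    generator, cross-entropy training with SGD and momentum, overlap metrics
    (Dice, Jaccard, precision, recall), and an ablation harness. All network
    computation runs on the CPU through a compact convolution engine built
    on 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    png,
    jpeg,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
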