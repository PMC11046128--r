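Package: morphoscreen
Title: Image-Based Morphological Profiling Screens Scored by CNN AUC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for image-based genetic screens built on
    five-channel Cell-Painting-style microscopy. Generates synthetic
    multi-channel fields with ground-truth, organelle-targeted perturbations;
    segments fields into single-cell crops and extracts per-cell morphological
    features; removes non-correlated cells with a Spearman rank-correlation
    filter; builds balanced, rotation/mirror-augmented train/validation/test
    datasets; trains a compact convolutional neural network per gene, channel
    and replicate and scores morphological variation as the test-set AUC; and
    aggregates AUC records into per-gene summaries, organelle attribution and
    prioritization of genes at shared GWAS loci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
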