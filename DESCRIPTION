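Package: hqcolony
Title: Quantum-Inspired Classification of Cell Colonies in Clonogenic Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Helstrom quantum classifier, a quantum-inspired
    binary classifier based on optimal discrimination of two quantum states,
    together with an area-based evaluation pipeline for clonogenic assays:
    gray-level co-occurrence texture feature maps (contrast, correlation,
    energy, homogeneity) and local entropy from well-plate images, ground-truth
    colony segmentation by spatial fuzzy c-means clustering with morphological
    cleanup, pixel-table dataset preparation (serialization, range
    normalization, random sampling, z-score standardization, development/test
    splitting), cross-validated hyperparameter search, a baseline-classifier
    comparison harness, and a seeded synthetic well-plate image generator for
    fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    EBImage,
    MASS,
    class,
    e1071,
    nnet,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    pROC,
    ranger,
    xgboost
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
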