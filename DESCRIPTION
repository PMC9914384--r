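Package: ecmpa
Title: Entropy-Controlled Marine Predators Algorithm for Deep-Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based selection of discriminative columns from fused
    deep-feature tables (such as concatenated DarkNet53/DenseNet201
    global-average-pool activations of white blood cell images) using a
    two-stage entropy-controlled marine predators algorithm (ECMPA): an
    unsupervised per-column Shannon-entropy filter followed by a marine
    predators metaheuristic over the retained dimensions with a
    k-nearest-neighbour holdout error as the fitness. Includes HSI-space
    colour histogram equalization for image preprocessing, serial feature
    fusion, a genetic-algorithm convergence baseline, KNN/SVM evaluation
    with confusion-matrix reporting, one-way ANOVA significance testing,
    and generators for synthetic fused-feature tables and cell-like images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
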