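Package: octanomaly
Title: Two-Stage AMD Detection from Retinal OCT B-Scans via L2-Constrained
    Embeddings and Local Outlier Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects age-related macular degeneration (AMD) in retinal optical
    coherence tomography (OCT) B-scans with a two-stage pipeline: a
    convolutional embedding network trained with an L2-constrained softmax
    loss maps images onto a hypersphere of radius alpha, and a from-scratch
    Local Outlier Factor (LOF) scorer classifies test images as normal or AMD
    by comparing each embedded test image against the reference population of
    normal training embeddings. Includes a seeded synthetic OCT B-scan
    generator (layered retina, drusen, sub-retinal fluid), confusion-matrix
    and ROC/AUC evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    readr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
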