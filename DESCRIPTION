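Package: panspecies
Title: Cross-Species Transfer Evaluation and Spatial Immune Prognostics for
    H&E Single-Cell Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well a single-cell H&E classifier trained
    on one species transfers to tumours of other species, and for AI-based
    spatial immune prognostication. Implements nuclear morphometry from
    labelled masks (27 shape and staining features), a t-SNE morphospace with
    a quantile-ladder overlap metric between cell-class groups, centroid-matched
    balanced-accuracy evaluation with cohort-level rank statistics, quadrat
    Morisita-Horn tumour-immune colocalisation, and multivariate Cox
    proportional-hazards prognostic models with lower-quartile dichotomisation.
    A synthetic-data module generates labelled nuclear images, classifier
    predictions with a known confusion structure, clustered spatial point
    patterns with tunable colocalisation, and survival cohorts from a known
    hazard model, so every stage is testable without whole-slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    Rtsne,
    survival,
    EBImage,
    e1071,
    generics,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
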