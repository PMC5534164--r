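Package: elcgap
Title: Ecogeographical Land Characterization and Germplasm Gap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gap analysis for crop-wild-relative germplasm collections:
    quality control of occurrence records (coordinate-precision filtering,
    georeferencing-quality scoring, 1-km spatial deduplication), random-forest
    selection of non-redundant ecogeographical variables, Ecogeographical Land
    Characterization (ELC) maps built by elbow-rule K-means clustering of
    bioclimatic, edaphic and geophysic raster layers, identification and
    priority ranking of spatial and ecogeographical gaps, and predictive
    characterization of candidate collection sites for drought and salinity
    tolerance via the Lang aridity index and topsoil salinity. Includes a
    synthetic-landscape generator with known ground truth so the whole
    pipeline is testable without external raster or occurrence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    sp,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
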