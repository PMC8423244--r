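Package: uavpheno
Title: Plot-Level Phenotyping from UAV RGB Orthomosaics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Radiometric calibration and plot-level trait extraction for
    field trials imaged with consumer RGB cameras on small UAVs. Fits the
    exponential empirical-line model that converts digital numbers to
    surface reflectance from ground calibration panels, computes six
    RGB-chromatic vegetation indices (EXG, EXGR, EXR, NDI, GLI, VARI),
    segments canopy from a dark mulch background by Otsu thresholding of
    the excess-green index, estimates per-plant canopy surface area and
    plant height from the canopy height model (DSM minus DTM), and runs
    the rank-based statistical layer used in plot trials: Shapiro-Wilk
    screening, Kruskal-Wallis tests, Dunn post hoc comparisons with
    Bonferroni adjustment and a compact letter display, Spearman
    correlation matrices, and correlation-matrix PCA. A seeded synthetic
    field generator renders georeferenced orthoimage, DSM and DTM rasters
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
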