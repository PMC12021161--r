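Package: herdscan
Title: Locating Active Nomadic Pastoralist Settlements in Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for finding active nomadic pastoralist
    settlements in satellite image tiles. Provides a seeded synthetic-scene
    simulator with georeferenced rasters, road and waterway networks and
    labeled tile manifests; tile-grid construction and a spatial-resolution
    degradation protocol; nearest-distance infrastructure covariates;
    class-conditional Gaussian (discriminant-analysis) models of
    infrastructure distance with Bayes-posterior auxiliary features and
    their fusion into a convolutional tile classifier; precision-recall
    evaluation (AUPRC, precision at fixed recall, top F1) with
    recall-calibrated thresholding; and region-scale scanning with
    detection merging and manual-review reduction reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
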