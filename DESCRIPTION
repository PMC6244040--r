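Package: phenocurves
Title: Plot-Scale UAV Field Phenotyping Traits and Growth-Curve Shape Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for plot-scale extraction of maize growth traits from
    multi-temporal field rasters and for shape-based analysis of their
    dynamics. Extracts plant height from crop surface models by vegetation
    segmentation (NGRDI/NDVI thresholding), neighbourhood maxima and ordinary
    kriging; computes canopy cover and mean NDVI per plot; derives growth-rate
    and contribution-rate traits between growth stages; screens lodging and
    low-emergence plots; summarises traits with a normality-gated coefficient
    of variation; clusters 4-stage trait time series with the k-Shape
    algorithm under the shape-based distance, selecting the cluster number by
    Davies-Bouldin and Dunn indices; and classifies per-cluster typical growth
    curves with a zenith/adjacent-point naming convention. Includes a seeded
    synthetic field-scene generator (rasters, plot polygons, labelled trait
    series with known ground truth) so the whole pipeline is testable without
    field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
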