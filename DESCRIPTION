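Package: pedopress
Title: Plantar Pressure Image Analysis and Foot-Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of color-coded plantar pressure images
    (pedobarography) for diabetic foot screening. Segments pressure regions from
    the red band of an RGB raster via histogram thresholding, area opening,
    morphological closing and hole filling; extracts connected pressure blobs
    with per-blob statistics; splits the pressure field into forefoot and
    hindfoot regions; and classifies the foot as hindfoot-dominant, balanced or
    forefoot-dominant from the forefoot-hindfoot pressure ratio. Also provides a
    synthetic pressure-image generator with exact ground-truth manifests, seeded
    k-means and agglomerative clustering with internal validity indices
    (silhouette, Davies-Bouldin, Dunn), and the classification and regression
    metrics used to score screening models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
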