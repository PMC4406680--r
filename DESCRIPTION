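Package: canopyseg
Title: Individual Tree Crown Delineation and Species Classification from
    Aerial Imagery and LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open re-implementation of a canopy-tree analysis workflow for
    tropical forests observed with very-high-resolution aerial imagery and
    discrete-return LiDAR. Derives digital terrain, surface and canopy height
    models from point clouds (iterative ground filtering, gridding, median
    smoothing); delineates individual tree crowns by multiresolution region
    merging and by watershed segmentation; scores delineations against
    reference polygons with over/under-segmentation rates and the closeness
    index D; computes first-order and grey-level co-occurrence (GLCM) texture
    bands and ranks them by gain ratio; classifies canopy species per pixel
    with maximum-likelihood and spectral-angle-mapper classifiers, reporting
    confusion-matrix accuracy measures; and compares airborne-derived crown
    widths and tree heights to field mensuration with nonparametric
    statistics. A seeded synthetic forest-scene generator (imagery, point
    cloud, ground truth) makes every stage testable without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    mgcv,
    EBImage,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
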