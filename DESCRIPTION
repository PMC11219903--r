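Package: clovermap
Title: Object-Based Mapping of Species Composition in Mixed Grass-Clover Swards
Version: 0.1.0
Authors@R:
    person("clovermap", "developers", email = "clovermap@example.org",
           role = c("aut", "cre"))
Description: An object-based image analysis (OBIA) toolchain for detecting and
    quantifying species composition (grass, clover, plantain, weeds) in
    very-high-resolution imagery of mixed swards. Provides a synthetic
    sward-scene generator with known ground truth, raster preprocessing
    (TIN-interpolated terrain models, canopy height models, HIS colour
    transform, vegetation indices, nearest-neighbour alignment), mean-shift
    segmentation with small-region merging, per-segment zonal statistics and
    polygon shape indices, reference-polygon labelling via spatial join,
    Random Forest classification under replicate-wise spatial
    cross-validation, and per-subplot cover-fraction estimation with
    regression against dry-matter-yield proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
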