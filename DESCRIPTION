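Package: vesselbench
Title: Synthetic Benchmarks and Evaluation Tools for 3D Vascular Network
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating 3D blood-vessel reconstruction
    pipelines on light-microscopy-style volumes: synthetic tubular phantoms
    with exact ground-truth centerlines, SWC skeleton and TIFF/NRRD volume
    input/output, rendering of radius-matched Gaussian supervision maps,
    a region-weighted L1 segmentation loss, dual-view ray geometry for
    interactive radius measurement, hollow-lumen filling of segmented trunk
    vessels, voxel-scooping and thinning centerline tracers, and
    centerline/branch-point matching metrics with graph, angle, density and
    signal statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    splines,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
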