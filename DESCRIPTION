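Package: morphmesh
Title: Morphometric Analysis of Segmented 3D Microscopy Objects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless morphometry toolbox for segmented volumetric microscopy.
    Converts integer-label TIFF stacks into closed triangle meshes by marching
    cubes, reads and writes Wavefront OBJ, and measures objects in physical
    units: surface area and enclosed volume, cross-sections along a center
    line with nine geometric properties per section, topology-preserving
    TEASAR-family skeletons serialized as SWC, straight and on-surface
    (geodesic-graph) distances, and angular distributions of objects around a
    reference point. A synthetic-shape generator with known analytic
    properties provides reproducible fixtures, and a command-line entry point
    wires the tools together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tibble,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    generics,
    rlang,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
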