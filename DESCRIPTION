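Package: boneshape
Title: Local Shape Analysis of Trabecular Bone with the Ellipsoid Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies local plate-like versus rod-like shape in 3D binary
    images of trabecular bone. Fits locally maximal ellipsoids into the image
    foreground by stochastic growth from distance-ridge and skeleton seed
    points, assigns each foreground voxel the ellipsoid factor
    EF = a/b - b/c of the largest containing ellipsoid, averages EF maps over
    repeated runs with convergence reporting, and draws Flinn (semi-axis
    ratio) plots. Also computes the mesh-based structure model index
    (SMI, SMI+, SMI-) by surface-dilation for comparison, and generates
    synthetic phantoms (spheres, rods, plates, gyroids, rod/plate lattices)
    with known ground truth so the whole pipeline is testable without image
    data. Reads and writes multi-page grayscale TIFF stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
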