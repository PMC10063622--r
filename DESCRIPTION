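Package: spiralmaze
Title: Double-Spiral Maze Design and Tracking Analytics for Minute-Insect
    Dispersal Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for dispersal assays of minute walking insects in
    back-lit double-spiral mazes. Generates parametric double-spiral
    arena geometries (centerline, walls, laser-cut outlines) and
    rasterized tunnel masks; simulates per-phase diffusive dispersal and
    renders ground-truthed image sequences; detects individuals by
    pack-wise temporal background subtraction and connected-particle
    analysis with shape descriptors; maps detections to a signed
    curvilinear coordinate by skeleton fragmentation and orthogonal
    projection; cleans detections with redundancy, size, edge and shape
    filters; and quantifies dispersal dynamics with mean squared
    displacement series, piecewise (segmented) regressions, dispersal
    type classification and the associated validation statistics (exact
    binomial detection-rate intervals, chi-square homogeneity,
    Monte-Carlo skewness symmetry tests, variance partitioning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
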