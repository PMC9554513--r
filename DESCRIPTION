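Package: elastishape
Title: Elastic and Linear Shape Analysis of Planar Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying objects by their outline shapes. Extracts
    closed contours from binary images (marching squares), resamples them to
    equally spaced points along a fitted spline, and aligns them by
    generalized Procrustes analysis. Shape distances are computed either in a
    linear eigenshape space (PCA of aligned semi-landmark coordinates) or on
    the square-root velocity function (SRVF) shape sphere, where geodesic
    distances are optimized over rotation, start point and elastic
    reparametrization by dynamic programming. Includes distance-matrix
    k-nearest-neighbour classification with stratified replicates and
    weighted F1 scoring, Karcher and linear mean shapes, geodesic shape
    transformation paths, class-average distance matrices, neighbour-joining
    trees, and a synthetic outline generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    clue,
    EBImage,
    isoband,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
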