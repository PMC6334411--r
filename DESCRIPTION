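Package: smlmtools
Title: Quantitative Analysis of Single-Molecule Localization Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Import, visualization and quantitative analysis of 2D
    single-molecule localization microscopy (SMLM/dSTORM/PALM) data.
    Localization tables (x, y, localization precision) are read from
    ThunderSTORM-style or generic delimited files, split into regions of
    interest, and rendered as per-localization Gaussian images or
    count-normalized kernel density estimates in localizations per square
    micrometre. Clusters of localizations are identified by binary-KDE image
    segmentation, DBSCAN, or Voronoi tile-area thresholding, quantified by
    shape features (FWHM, convex hull area, elongation, principal-axis
    orientation), and scored against ground truth from a built-in synthetic
    benchmark generator. Feature-based, template-free particle averaging
    aligns many copies of a structure by centre of mass and principal axis
    to reveal common ultrastructure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
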