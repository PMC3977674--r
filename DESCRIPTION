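Package: froa
Title: Fixation Region Overlap Analysis of Shape-Feature Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing where observers fixate on 2D object
    silhouettes. Builds theoretical regions of interest from shape
    geometry (concave and convex bounding contour via signed curvature,
    internal part boundaries via the minima/short-cut rule), compares
    fixation-derived regions against them with the Fixation Region
    Overlap Analysis (FROA) Monte-Carlo statistic (model matching
    correspondence, MMC), computes scanpath metrics (saccade amplitude
    in degrees of visual angle, dwell time), and runs the group-level
    split-plot ANOVA and comparison tests. Includes seeded synthetic
    generators for multi-part silhouettes with known junction chords and
    for scanpaths with a controllable region-of-interest preference, so
    the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Visualization, CellBasedAssays
RoxygenNote: 7.3.3
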