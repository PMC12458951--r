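Package: immunospat
Title: Spatial Analysis of Immune Clusters in Multiplexed Whole-Slide Cell Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the spatial immune microenvironment of
    solid tumors from multiplexed-immunofluorescence cell tables. Detects
    B-cell immune clusters (BICs) by two-stage K-nearest-neighbour nucleation
    and expansion and T-cell clusters (TICs) by density-based clustering,
    scores cluster organization with the ICAT dispersion statistic, computes
    windowed centered and multitype Besag L-function summaries (clustering
    intensity, R50, effective clustering radius), quantifies lymphocyte
    infiltration density over union-of-disk tissue areas, and runs the
    associated proximity, contact and cohort-level statistical comparisons.
    Includes a synthetic-specimen generator with planted ground truth for
    validation, and a single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    spatstat.geom,
    spatstat.explore,
    RANN,
    ica,
    igraph,
    sp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
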