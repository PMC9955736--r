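Package: csacal
Title: Colorimetric Sensor Array Calibration of Meat Freshness (TVB-N)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration of total volatile basic nitrogen (TVB-N),
    the standard meat-spoilage index, from colorimetric sensor array (CSA)
    scans. Extracts 90-variable colour-difference fingerprints (RGB, HSV,
    CIELAB deltas plus an RGB Euclidean magnitude over a 3x3 dye grid) from
    before/after headspace-exposure images, partitions samples with SPXY
    (joint x-y distance max-min selection), fits linear PLS and nonlinear
    epsilon-SVR (RBF kernel, grid-searched) calibrations, screens variables
    with UVE, CARS and random frog, diagnoses nonlinearity with a
    Wald-Wolfowitz runs test, and reports Rc, RMSEC, Rp, RMSEP and RPD per
    model. Includes a synthetic-data generator emulating the study design
    (80 samples over an 11-day storage, sparse nonlinear dye response) so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    kernlab,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
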