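Package: gpical
Title: Non-Destructive Chlorophyll Quantification from Digital Images by
    Green Pixel Intensity Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates chlorophyll a, b and total chlorophyll of microalgal
    cultures non-destructively from digital photographs. Extracts
    background- and baseline-corrected green pixel intensity (G/(R+G+B))
    from annotated flask images, computes solvent-extraction reference
    concentrations from spectrophotometer absorbances (Porra
    coefficients), builds and validates linear standard curves (automatic
    linear-interval detection, 95 percent confidence bands, limit of
    blank, limit of detection, percent relative standard deviation),
    performs inverse prediction with dilution flags, and statistically
    compares calibration curves across environmental conditions
    (ANCOVA-style slope and intercept F-tests, interference error tables,
    sensitivity power analysis). Includes a seeded synthetic-data and
    flask-image renderer so the whole pipeline can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
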