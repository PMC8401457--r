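Package: ecisgrowth
Title: Modelling and Quantification of Impedance-Based Cell Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Import, edit and normalize electric cell-substrate impedance
    sensing (ECIS) well-plate growth curves (impedance versus time), fit
    smoothing-spline, four-parameter logistic and segmented (broken-line)
    regression models per well with automatic starting and smoothness
    parameters, extract quantitative curve reference points (first and
    second derivative maxima, fractional-rise times, segmentation knots),
    integrate the area under the curve by composite Simpson's rule, and run
    downstream comparison statistics (exponential trend models across
    dilution series, Akaike-weight model comparison, Welch t-tests with
    Bonferroni correction). Includes a deterministic generator of synthetic
    five-phase growth curves for validation, a plotting helper and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    readxl,
    jsonlite,
    zip
Suggests:
    testthat (>= 3.0.0),
    segmented
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
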