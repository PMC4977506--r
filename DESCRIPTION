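Package: sapdetect
Title: Automated Detection of Stretch-Attend Posture in Overhead Rodent Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Detects stretch-attend posture (SAP), a rodent risk-assessment
    behavior, in overhead grayscale videos stored as multi-page TIFF stacks
    with a rodent-free background as the last page. The pipeline subtracts
    the background, binarizes, removes the tail by morphological opening,
    selects the largest connected component, fits an ellipse from image
    moments, and gates frames on ellipse eccentricity and centroid speed
    with a minimum-bout filter. Includes evaluation statistics against
    human rater panels (majority-vote consensus, confusion metrics with
    Wald intervals, F-score, Matthews correlation coefficient, ROC curves
    with trapezoidal AUC, threshold optimization, and two-way
    average-measure intraclass correlation) and a calibrated synthetic
    video generator with analytic ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    tiff,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
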