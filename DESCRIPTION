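Package: orthocal
Title: Colour Calibration and Homogeneity Assessment for UAV Orthophoto Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiometric colour calibration of UAV survey imagery with
    three-dimensional thin-plate splines fitted to a 24-patch ColorChecker
    chart, landmark-based superimposition of orthophoto stacks via
    generalized Procrustes consensus and 2D thin-plate-spline unwarping,
    and a colour-homogeneity statistic (per-point root-mean-square of the
    across-image channel standard deviations) compared between calibrated
    and uncalibrated conditions with a paired Wilcoxon signed-rank test.
    Includes a synthetic UAV-survey generator with known ground truth and
    closed-form photogrammetric flight-geometry calculators (overlap,
    sidelap, ground sample distance).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
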