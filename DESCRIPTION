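Package: fieldchm
Title: Crop Height and Growth Dynamics from UAV LiDAR Point Clouds in
    Field-Plot Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fast extraction of per-plot crop height and growth dynamics
    from repeated UAV LiDAR scans of field-plot trials. Point clouds are
    filtered, rasterized to 16-bit elevation images, segmented into
    individual field plots by projection profiles, rectified for
    parallelogram skew, and converted to canopy height models by maximum
    filtering and subtraction of the time-zero ground surface. Per-plot
    height statistics feed relative growth rates and three-parameter
    logistic growth-curve fits. Includes a synthetic field generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
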