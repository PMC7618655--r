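Package: kneemark
Title: Two-Stage Hourglass Landmark Localization and Tibiofemoral Angle
    Measurement in Knee Radiographs
Version: 0.1.0
Authors@R:
    person("kneemark", "developers", email = "kneemark@example.org",
           role = c("aut", "cre"))
Description: Automated varus/valgus knee-alignment measurement from
    anteroposterior knee radiographs. Localizes anatomical landmarks with a
    two-stage (global then local) attention-gated hourglass heatmap network
    trained with a wing loss on soft-argmax coordinates, derives the anatomical
    tibiofemoral angle (aTFA) from shaft/notch landmark midpoints (FTS and
    FNTS constructions), and evaluates localization (relative point-to-point
    and point-to-curve distances) and method agreement (ICC(2,1), mean
    absolute difference, Bland-Altman). Includes a synthetic left-knee phantom
    generator with exact landmark ground truth and configurable true aTFA so
    the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
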