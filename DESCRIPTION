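Package: embodir
Title: Analysis of Artificial-Limb Embodiment Experiments in Head-Fixed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for the behavioral-statistics analysis of rubber-hand-illusion
    experiments in head-fixed mice: reading and writing markerless pose-tracking
    tables, signal preprocessing (gap interpolation, baseline and pre-threat
    normalization, pupil diameter, point speed), condition-contrast difference
    traces with a baseline-segment maximum-statistic bootstrap for family-wise
    error control, significance-window detection, paired Wilcoxon signed-rank
    testing with exact small-sample p-values, and a difference-of-differences
    contrast between experiments. Includes a synthetic cohort generator that
    emulates the trial timeline, stroke schedules and condition-dependent gaze
    responses, so the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
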