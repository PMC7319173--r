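Package: sealdive
Title: Movement, Dive and Haul-Out Analysis for Ice-Seal Biologging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing satellite biologging data from ice seals:
    plausibility filtering of Argos location fixes, track interpolation with a
    continuous-time correlated random walk state-space model fitted by Kalman
    filtering, bathymetry and sea-ice habitat annotation on an equal-area grid,
    time-depth-recorder dive-bout segmentation into resting, repetitive and
    mixed diving, haul-out detection from hourly wet/dry sensor summaries, diel
    activity profiles, and extrapolation of monthly activity budgets from
    partially sampled sensor streams.  A synthetic-data generator with known
    ground truth (tracks, dive series, wet/dry series, bathymetry and daily
    sea-ice rasters) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
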