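Package: offsync
Title: OFF-Period Detection and Synchrony Analysis for Cortical Multichannel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bistable cortical population activity in
    sleep: multi-unit spike detection from wideband traces (MAD noise
    estimation, common median reference), single-channel and population
    ON/OFF-period segmentation with quorum rules, multitaper (DPSS)
    slow-wave-activity and band-power estimation, spike-time tiling
    coefficient synchrony matrices with Fisher-Z aggregation, OFF-locked
    field-potential slope and amplitude metrics, vigilance-state condition
    extraction, optogenetic stimulation protocol generation, video-pose
    actigraphy sleep estimation, and a synthetic session generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
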