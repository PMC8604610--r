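Package: mousegait
Title: Autonomous Gait Detection and Analysis for Mice on a Glass Trackway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects illuminated mouse footfalls in glass-trackway video
    frames by green-channel thresholding, Euclidean proximity clustering and
    cluster-size filtering; classifies footfalls into the four paws and
    propagates labels across frames; extracts the standard gait parameters
    (run duration, cadence, stride length, stance, swing, duty cycle, paw
    supports, paw area and intensity); and evaluates detection quality with
    Hit:Miss:False scoring and cell-based ROC analysis. Ships a synthetic
    trackway-run generator with exact ground truth so the full pipeline is
    testable end to end without real videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    png,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
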