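Package: flysocial
Title: Tracking-by-Detection and Social-Behavior Metrics for Grouped Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links per-frame fly detections into identity-stable trajectories
    with a greedy distance-sort rule, classifies chase/courtship events either
    from detector-labeled boxes or kinematically from trajectories, aggregates
    per-frame chase relations into chaining records, and computes the standard
    quantitative readouts of Drosophila group behavior: behavior indexes
    (Index = B(d)/B(max) x 100), courtship index, time-based chaining index,
    two-choice preference, social space, encounter counts, foraging visits and
    dwell, and locomotion states. An agent-based arena simulator generates
    detection streams with full ground truth in place of video, and rendering
    helpers produce event maps, occupancy heatmaps, and per-frame chaining
    series with their underlying numeric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    igraph,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
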