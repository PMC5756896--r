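Package: songscape
Title: Spatiotemporal Analysis of Acoustic Interactions Between Territorial Songbirds
Version: 0.1.0
Authors@R: person("Song", "Scape", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study fine-scale acoustic interactions between
    territorial songbirds recorded with multiple microphone arrays.
    Triangulates 2D song locations from per-array direction-of-arrival
    (DOA) event streams with spatial and temporal gating, assembles
    per-individual song timelines via song-post assignment, scores
    timelines against human annotations (TP/FP/TN/FN durations, accuracy,
    ROC rates), and quantifies temporal overlap avoidance and directional
    influence between individuals using duty-cycle-preserving gap-shuffle
    randomization tests, asymmetric active-overlap tests, plug-in transfer
    entropy on binarized song series, and session-level bootstraps. A
    synthetic-soundscape generator produces ground-truth timelines with
    controllable interaction structure and the noisy DOA events they would
    yield, so the whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
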