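Package: synergait
Title: Muscle-Synergy Analysis and Personalized Multi-Channel FES Design for Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gait muscle synergies from surface-EMG envelopes by
    non-negative matrix factorization with multiplicative updates, reconstructs
    a patient's envelopes against a healthy synergy template with one factor
    held fixed (non-negative matrix reconstruction, NNR), scores each synergy
    with four impairment metrics against mean minus two standard deviation
    normative thresholds, builds a personalized multi-channel functional
    electrical stimulation (FES) strategy from the impaired synergies, and
    simulates the real-time warping of the stimulation profiles onto a
    six-phase gait timeline driven by initial-contact, end-contact and
    mid-swing events. Includes a synthetic-data generator for healthy cohorts,
    stroke-like patients and gait-event streams so the whole pipeline runs
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
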