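Package: mstkit
Title: Trial Scheduling, Scoring, and Reliability Simulation for the
    Mnemonic Similarity Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses the Mnemonic Similarity Task (MST), a
    recognition-memory paradigm with repeated items, highly similar lures,
    and novel foils that is widely used to assay hippocampal pattern
    separation.  Provides stimulus-bank modelling with difficulty-matched
    subset construction, trial-schedule generation for study-test and
    continuous formats at full and reduced lengths (lag-banded continuous
    designs, guided practice blocks, session counterbalancing, duration
    accounting), scoring of response logs into the task's standard outcome
    measures (lure discrimination index, corrected recognition, and
    signal-detection d-prime variants) with validity filtering, a
    generative signal-detection participant simulator with trait stability
    across sessions, and the psychometric analysis layer used to compare
    task variants: robust regression with FDR-based outlier flagging,
    Fisher r-to-z comparisons, sample-size computation for correlations,
    effect sizes, nested-regression F-tests, and cross-variant score
    conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
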