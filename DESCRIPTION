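Package: unblockr
Title: Single-Unit Analysis of Pavlovian Odor Unblocking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-aligned single-unit electrophysiology recorded
    during Pavlovian odor unblocking. Provides a data model and delimited-text
    readers for event and spike-timestamp tables, epoch-normalized firing
    rates (period minus inter-trial-interval), Bonferroni-screened odor
    responsiveness and classification of units into salience and
    outcome-predictive categories, trial-by-sliding-window differential
    firing maps with per-cell significance, cue- and outcome-selectivity
    indices with regression analyses, behavioral measures (response latency,
    probe-test well time, two-bottle preference ratios), and a ground-truth
    labelled inhomogeneous-Poisson spike-train generator that emulates the
    task so the full pipeline can be exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
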