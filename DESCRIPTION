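Package: gazesrt
Title: Automated Extraction of Saccadic Reaction Times from Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting saccadic reaction times (SRTs) from raw
    corneal-reflection eye-tracking recordings of the two-stimulus
    (gap/baseline/overlap) attention-disengagement paradigm. Implements
    forward-continuation interpolation of missing-data gaps, moving median
    filtering, area-of-interest based saccade detection, post-analysis
    verification checks (stimulus durations, interpolation cap, border
    violation, minimum fixation), per-condition mean SRTs and the
    dwell-time SRT index, and trial-level data-quality metrics (precision,
    robustness). A synthetic gaze-trace generator with known ground truth
    makes every stage verifiable without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
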