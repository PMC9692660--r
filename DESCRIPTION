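Package: periofuse
Title: Multimodal Fusion of Periocular Eye-Tracking Signals for Demographic Classification
Version: 0.1.0
Authors@R:
    person("Perio", "Fuse", email = "maintainer@periofuse.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating age group and gender from
    periocular signals recorded by a remote eye tracker. Raw gaze logs are
    filtered by per-eye validity codes, segmented into blinks (with a
    fast-blink counter) and dispersion-based fixations, and summarized into
    per-stimulus statistical descriptors for three modalities (pupil
    diameter, blinks, fixations). Modalities are combined by feature-level
    concatenation with max-absolute scaling and by score-level fusion:
    weighted sum, weighted product, a pairwise Bayes rule with a brute-force
    w/10 weight grid, and classifier-based fusion of concatenated confidence
    scores. Includes a configurable synthetic-cohort generator emulating a
    Tobii-style 50 Hz export with demographic effect structure, a compact
    classifier zoo with exhaustive parameter search and variable-k
    cross-validation, and an end-to-end seeded experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
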