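Package: fasctools
Title: Fasciculation Quantification from High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of fasciculation potentials in
    high-density surface electromyography (HDSEMG) grid recordings. Implements a
    noise-responsive amplitude-threshold detection pipeline (per-channel
    extreme-amplitude screening, super-channel assembly, flanking-window noise
    bands, an 8x-noise inclusion threshold and 5-second noisy-block rejection),
    block-based identification and exclusion of voluntary motor-unit activity
    with sensitive (10 s) and specific (1 s) strategies, an interval-statistics
    bagged-trees classifier that rescues falsely flagged blocks, summary metrics
    such as the fasciculation frequency, and a fully seeded synthetic grid-EMG
    generator with per-spike ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
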