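Package: piradl
Title: Activity-of-Daily-Living Recognition from Ambient PIR Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognises activities of daily living (ADL) in single-resident
    smart homes instrumented with wireless sensor boxes measuring passive
    infrared (PIR) motion, temperature, luminescence, humidity and
    acceleration at 0.2 Hz. Provides a semi-Markov synthetic-home simulator
    with visitor and overlapping-activity episodes, 5-second feature-grid
    preprocessing with room mapping, PIR-constellation token segmentation,
    refined room-based segmentation using weighted moving-average filters
    with edge preservation and a short-activity filter, naive Bayes, support
    vector machine and random-forest episode classifiers with a parallel
    visitor detector, a fixed 60-second time-slot baseline, and
    leave-one-home-out evaluation reporting per-activity sensitivity,
    specificity, precision and F-measure on 5-second time slices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
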