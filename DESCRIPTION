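Package: blinkengage
Title: Blink-Rate Measures of Viewer Engagement with Scene Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying viewer engagement from spontaneous
    eye-blink inhibition in task-manipulated viewing studies. Provides
    blink detection from pupillometry traces, per-scene and interval
    blink-rate metrics, content-aware ROC classification of task group,
    content-unaware leave-one-out SVM classification of attended-scene
    parity with permutation testing, kernel-density likelihood-ratio
    measures of classification strength, the accompanying inferential
    statistics, and a synthetic-cohort generator with task-locked blink
    suppression so the full pipeline is testable without eye-tracking
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
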