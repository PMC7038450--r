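Package: pressmmg
Title: Forehead Textile Pressure Mechanomyography Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for forehead surface pressure
    mechanomyography recorded with a 2x10 textile pressure-mapping (TPM)
    headband. Segments pressure-frame streams into analysis windows,
    reduces each window to eight key frames, extracts image-moment
    features (three second-order central moments plus Hu's seven moment
    invariants per key frame, 80 features per window), classifies
    mimicked facial expressions (eyebrow states, seven emotions, and
    eyebrow-based emotion groups), scores dual N-back working-memory
    sessions, and tests feature histograms against stimulus/input
    conditions with a balanced two-histogram chi-square statistic.
    Includes a synthetic-data generator that emulates both experiment
    protocols for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
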