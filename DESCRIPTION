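Package: affsync
Title: Affective Synchrony Scene Detection for Multimodal Behavior Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-anchored behavioral annotation streams
    produced by multimodal recognizers (speech sentiment, categorical facial
    emotion, continuous valence, smiling). Provides a typed annotation-tier
    data model with validation and flat-file I/O, interval binning and
    majority-vote fusion of recognizer ensembles, rule-based classification of
    intrapersonal affective (a)synchrony between verbal sentiment and
    non-verbal affect with duration and coverage filters and seeded scene
    selection, a generic sliding-window scene-search engine instantiated as a
    smile-mirroring detector for dyadic interactions, inter-rater agreement
    statistics (Cohen's kappa, Cronbach's alpha), and a synthetic session
    generator with planted ground truth for end-to-end testing without any
    recordings or pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
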