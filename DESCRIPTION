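Package: moodsense
Title: Smartphone Passive-Sensing Features and Depressed-Mood Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping of depressed mood from smartphone
    data. Parses and validates per-participant passive-sensor tables (screen
    on/off events, GPS fixes, activity-transition events, facial-expression
    embeddings) and self-report questionnaires (PHQ-9, CESD-R), derives a
    33-dimensional multimodal feature vector (screen-off sleep proxy and usage
    statistics, DBSCAN-based location entropy and location variance, mean
    daily physical-activity time, aggregated expression embedding), trains a
    random-forest depressed-mood classifier under a single 3:1 split protocol,
    and evaluates predictions against questionnaire cut-point labels and
    clinician diagnosis. Includes a synthetic-cohort generator with a
    controllable latent depressed state so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
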