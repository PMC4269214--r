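Package: stresspipe
Title: Day-and-Night Stress Assessment from Smartphone Logs and Nocturnal
    Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts behavioral features from smartphone day logs (calls,
    calendar, contacts, battery, accelerometer, GPS, voice responses) and
    heart-rate-variability features from chest-belt RR intervals recorded
    during sleep, and models a three-level perceived-stress class with a
    multinomial logistic regression. Provides a continuous daily stress
    score, a low-pass-filtered long-term stress score, modality fusion when
    only one data source is available, correlation-based feature reduction,
    per-user sequential forward feature selection, leave-one-day-out and
    leave-one-participant-out cross-validation, a seeded synthetic-cohort
    generator with known ground truth, and an end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    nnet,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
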