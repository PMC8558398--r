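Package: remidetect
Title: Reduced-Channel Wearable EEG Seizure Detection and Review Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Seizure-event detection for reduced-channel wearable EEG.
    Builds the 10-channel montage (four referential scalp sensors plus six
    sensor-to-sensor differentials) from single-channel EDF recordings,
    generates seeded sensor-realistic synthetic cohorts with ground-truth
    focal seizures, extracts per-2-s-segment features in the time, frequency,
    time-frequency and complexity domains, trains a bootstrapped 500-tree
    random-forest segment classifier under leave-one-subject-out
    cross-validation, forms seizure events from the classifier likelihood via
    a leaky weighted integrator with run-length triggering and merge/discard
    post-processing, and evaluates detections with any-overlap event scoring
    (sensitivity, precision, false detections per hour, percent overlap),
    patient-level rule-in metrics, 2-of-3 reviewer consensus and
    Cohen's/Fleiss' kappa inter-rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
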