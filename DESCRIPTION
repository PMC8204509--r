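Package: drivemarkers
Title: GPS Driving Digital Biomarkers for Preclinical Alzheimer Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts driving-space and driving-performance indicators from
    in-vehicle GPS logs sampled every 30 seconds (trip segmentation, distances,
    radius of gyration, destination entropy, night trips, hard braking, jerk),
    labels preclinical Alzheimer disease from the CSF Abeta42/Abeta40 ratio, and
    classifies participant-months with Random-Forest models evaluated by
    precision, recall, F1, ROC/AUC with bootstrap confidence intervals and Gini
    feature importance. Includes a calibrated synthetic naturalistic-driving
    cohort generator so the full pipeline is testable end to end without access
    to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    ranger,
    MASS,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
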