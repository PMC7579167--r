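Package: stressmapr
Title: Detecting and Mapping Moments of Stress from Wearable Biosensor Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mixed-methods urban stress mapping from wearable
    sensor field campaigns. Ingests galvanic skin response (GSR) and skin
    temperature (ST) traces, GPS tracks and geotagged emotion-diary entries;
    applies zero-phase Butterworth filtering to separate the phasic GSR
    component from tonic baseline; detects moments of stress with a
    rule-based template (sustained GSR rise with a minimum slope angle,
    followed by a lagged skin-temperature drop); georeferences detections by
    time-matching against the GPS track; aggregates standardized stress
    rates to a metric grid and computes Getis-Ord Gi* hot/cold-spot
    classifications, sensor-versus-diary difference maps and pre-post
    campaign comparisons. Includes a synthetic campaign generator with
    planted, annotated stress responses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
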