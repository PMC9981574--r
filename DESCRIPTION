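Package: DaphniaTrack
Title: High-Throughput Video Tracking and Ecotoxicological Analysis of
    Daphnia magna Locomotion
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automatic video tracking pipeline for locomotory analysis of
    Daphnia magna in aquatic toxicity testing. Detects swimming animals by
    rolling-mean background subtraction with automatic 2-means threshold
    selection, removes non-animal objects with a patch classifier (random
    forest or support vector machine on Sobel edge features), links
    detections across frames with a SORT-style Kalman/Hungarian tracker
    using a mixed IOU and centroid-distance association cost, and derives
    behavioural endpoints (per-frame displacement, immobility, radius of
    activity) and dose-response summaries (log-logistic EC50). Includes a
    seeded synthetic-scene generator with ground truth and CLEAR MOT /
    identity tracking metrics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    clue,
    randomForest,
    e1071,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
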