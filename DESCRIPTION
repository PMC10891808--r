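Package: pentrack
Title: Multi-Object Tracking for Livestock Pen Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detector-agnostic multi-object tracking toolkit for fixed-camera
    livestock pens. Implements a history-buffered customized tracking algorithm
    (CTA) that re-identifies cattle after miss detections and occlusions, seven
    reference trackers (SORT, Deep SORT association core, a modified Deep SORT
    re-identification rule, ByteTrack-style two-stage association, centroid,
    centroid with Kalman filter, and plain IOU tracking), detection-stream
    cleanup by box-area thresholds and region-of-interest masking, MOTChallenge
    input/output, MOTA-based evaluation, and a synthetic pen-scenario generator
    that reproduces detection dropouts, static-object occlusion, and cow-cow
    occlusion without any video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
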