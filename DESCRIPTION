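Package: cagecount
Title: Cage-Level Chicken Counting from Inspection Detection Streams
Version: 0.1.0
Authors@R: person("Cagecount", "Developers", email = "cagecount@example.org",
    role = c("aut", "cre"))
Description: Detector-agnostic engine for counting caged laying hens from
    per-frame bounding-box detections produced by a moving inspection camera.
    Reads detection streams in JSON-lines, COCO-style JSON or per-frame YOLO
    text dialects; segments the stream into cages using pairs of detected
    fence railings and an N-consecutive-frame transition rule; filters
    chicken-head detections to the lateral span of the cage and reports each
    cage's maximum head count, key frame and timestamp. Ships detection and
    counting evaluation statistics (precision, recall, F1, AP50:95, sample
    selection, chicken selection and chicken recognition rates), a
    ground-truthed synthetic inspection-stream simulator with a configurable
    detector-noise model, and training-free reference implementations of
    coordinate attention and additive reversible network blocks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
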