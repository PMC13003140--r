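Package: sisegment
Title: Annotation-Free Surgical Instrument Segmentation via Anomaly-Guided
    Point Prompts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments surgical instruments in endoscopic, microscopic and
    OCT/ultrasound-style images without annotated training data. A memory
    bank of patch features from instrument-free images yields a per-pixel
    anomaly map; domain color/intensity filters turn it into a surgical
    instrument score map whose maxima become point prompts for a promptable
    segmenter; three candidate masks are scored against the binarized
    instrument map and the best is kept. Includes seeded synthetic scene
    generators for both image domains, uncertainty-aware evaluation metrics
    (IoU, DICE, normalized surface distance, prompt accuracy), and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
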