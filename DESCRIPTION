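Package: operantr
Title: Simulation, Synchronization and Signal-Detection Analysis of
    Trial-Based Operant Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A hardware-free re-implementation of a modular behavioral
    platform for rodent psychophysics: an event-driven finite-state task
    engine for head-fixed closed-loop and freely moving operant paradigms,
    a constrained stochastic trial scheduler, a two-clock synchronization
    layer that assembles standardized per-trial records, signal-detection
    performance and side-bias analysis (d-prime, criterion, learning and
    bias-correction rules), and a two-stage pupillometry pipeline
    (open/occluded frame classification followed by circular pupil
    segmentation). A parametric virtual rig - simulated device clocks,
    encoder and camera streams, synthetic eye frames, and a
    signal-detection virtual mouse - makes every stage testable without
    hardware or animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    MASS,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
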