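Package: finepitch
Title: Virtual Fine-Pitch Diode-Array Measurements for SRS Dose QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and scores a patient-specific quality-assurance workflow for
    stereotactic radiosurgery in which a coarse-pitch semiconductor diode array is
    read out repeatedly under small treatment-couch translations and the shifted
    acquisitions are merged into a single virtual fine-pitch measurement. Provides
    steep-gradient synthetic reference dose distributions (single 1 cm target and
    single-isocenter two-target geometries), diode sampling with anisotropic
    active-area averaging and measurement noise, couch-shift schedule planning and
    dataset merging, profile root-mean-square-error and 2D gamma-index scoring, and
    a one-command replication experiment relating virtual detector spacing to
    profile and gamma agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
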