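Package: ppmap
Title: Point Projection Mapping Calibration and Histology Label Transfer
Version: 0.1.0
Authors@R: person("PPM", "Maintainers", email = "ppmap@example.org", role = c("aut", "cre"))
Description: Tools for validating point-based optical tissue measurements
    against annotated histopathology. Implements depth-camera base-plane
    calibration by linear least squares, rigid camera-to-projector transform
    estimation from 3D point pairs, mutual-information-driven deformable
    registration of specimen snapshots to histology images via dense
    displacement fields, and transfer of probe-sized measurement areas into
    annotated histology space to produce per-location tissue-label
    percentages. Includes a deterministic synthetic phantom generator and a
    command-line pipeline so every stage can be exercised without hardware
    or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
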