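Package: fiducial3d
Title: Automatic Fiducial Landmark Localization on Textured 3D Head Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Localizes the three anatomical fiducial landmarks (nasion and
    the left and right preauricular points) on a textured triangle-mesh head
    scan, as used to anchor EEG electrode digitization. The pipeline corrects
    the gravity-aligned orientation of scanner output, renders orthographic
    2D projections of the head over a full 360-degree azimuth sweep, runs
    pluggable face/eye/nose/mouth/ear detectors on each view, selects the
    best frontal view from the continuous detection arc, estimates the
    nasion and preauricular pixel coordinates from detector bounding-box
    geometry, reprojects those pixels onto the mesh surface by ray casting,
    and builds the CTF subject coordinate system from the recovered 3D
    points. Includes cascade-classifier false-alarm-rate arithmetic for
    FAR-ordered detector ladders, a deterministic synthetic-head generator
    with known ground truth, and oracle detectors so the full pipeline is
    testable without trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
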