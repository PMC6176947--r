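Package: craniokin
Title: Neurocranial Kinematics and Axis-of-Rotation Localization from
    Marker Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring three-dimensional motion of the fish
    neurocranium relative to a body plane from tracked marker
    trajectories, as used in studies of suction feeding. Estimates
    per-frame rigid-body poses by orthogonal Procrustes alignment,
    decomposes neurocranium motion into elevation, yaw and roll through
    joint coordinate systems (JCS), and locates the axis of rotation
    (AOR) of neurocranial elevation by a grid of candidate JCS
    placements that minimizes translation. Includes the classical 2D
    Reuleaux perpendicular-bisector estimator for comparison, and a
    synthetic-strike simulator with known ground truth for validating
    both methods on planar and non-planar motion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
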