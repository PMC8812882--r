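Package: podtrack
Title: Overhead-Camera Tracking and Kinematic Analysis of Marine Mammal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring groups of marine mammals (such as bottlenose
    dolphins) with fixed overhead cameras. Per-frame bounding-box detections
    from two partially overlapping cameras are projected into a common metric
    world frame via planar homographies, cross-camera duplicates are meshed
    with distance-based weights, and the meshed detections are linked into
    tracklets with a constant-velocity Kalman filter. Tracklets yield speed,
    yaw and yaw-rate series that are accumulated into uncertainty-aware
    habitat occupancy, speed and direction maps, and summarised per time
    block by joint differential entropy of speed and yaw (a kinematic
    diversity proxy) and two-sample Kolmogorov-Smirnov comparisons. A
    synthetic habitat simulator generates ground-truth trajectories and
    noisy two-camera detection streams so the whole pipeline can be
    exercised and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    zoo,
    signal,
    mgcv,
    withr,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
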