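# podtrack

Camera-based tracking and kinematic analysis of marine mammal groups in
managed habitats.

Zoos and aquariums increasingly monitor bottlenose dolphins and other
cetaceans with fixed overhead cameras. Object detectors can mark animals
in every frame, but raw per-frame boxes from two partially overlapping
cameras are not yet science: they must be fused into a single metric
world frame, linked through time into trajectories, and reduced to
quantities a behavioral researcher can compare across conditions —
habitat-use maps, swimming kinematics, and statistics that separate
training-session from free-swim behavior. `podtrack` implements that
full post-detection pipeline, plus a synthetic habitat simulator that
generates ground-truth trajectories and realistic two-camera detection
streams so every stage can be validated without any video data.

## The method

**Camera fusion.** Each camera's image plane is related to the habitat
surface (the *world frame*, x along the 33.5 m length, y along the
12.2 m width) by a planar homography estimated from point
correspondences with the normalized Direct Linear Transform. Detection
boxes are projected into the world frame; where the two cameras overlap,
conflicting boxes are paired by mutual-best polygon IoU and their
centroids meshed with distance-based weights. With `d_b` the x-distance
from detection `u` to the nearest projected camera boundary `b_n`, and
`d_l` the x-distance from the overlap midline `l_s` to `b_n`, the
near camera's weight is

```
w_n = d_b / (2 d_l),   w_f = 1 - w_n
```

so weights are equal on the midline and the near (most oblique) camera's
vote vanishes at its own field-of-view edge.

**Tracklets.** Meshed detections are linked frame to frame by a
constant-velocity Kalman filter: each active tracklet predicts its next
position (`p̂ = p + v Δt` at 10 Hz), claims the closest detection within
a 0.8 m proximity gate, and updates on it. Unassociated tracklets coast
on the prediction, bridging detection gaps of up to 4 frames; after 5
consecutive misses a tracklet is deactivated and truncated at its last
confirmed association. Differentiating the filtered states yields speed
`v`, yaw `θ = atan2(v_y, v_x)` and yaw rate `θ̇`, and a static/dynamic
movement split at 0.5 m/s.

**Uncertainty-aware maps.** Animal depth is unobservable from a single
overhead view, so each detection's position error is anisotropic: a
Gaussian minor axis (`σ = 0.2 m`, the camera detection error) and a
major axis built by resampling a prior depth-occupancy PDF to the
detection's maximum depth-induced displacement `e_m = s·d_max·r/h_c`
(pinhole similar triangles at scale `s` = 20 px/m), convolving with the
minor kernel, rotating the outer-product kernel `E = D1ᵀD2` to the error
direction `ψ_m`, and truncating at the habitat wall. Kernels are
injected (centred at the half-error offset) into occupancy `M`,
speed-weighted `N`, and direction maps `Qx`, `Qy`; `S = N ⊘ M` is the
mean-speed map.

**Block statistics.** Kinematic samples are partitioned into the daily
schedule of out-of-training (OTS) and in-training (ITS) blocks. Per
block, the joint differential entropy of speed and yaw

```
h(S, Ψ) = −∫ f(s, ψ) ln f(s, ψ) ds dψ
```

is estimated from a 64×64 histogram of 1e5 subsamples (a
kinematic-diversity proxy), and all same-type block pairs are compared
with two-sample Kolmogorov–Smirnov tests (1e4 subsamples per side, six
metrics: speed, yaw, yaw rate and their rolling standard deviations) at
a significance threshold of α = 0.001.

## Worked example

Run the bundled 30-minute synthetic "pseudo-day" (7 animals, 10 Hz,
0.1 m detection noise, 20% dropout, five OTS and four ITS blocks with
distinct behavior mixes):

```r
library(podtrack)

dir <- tempfile(); fxd <- file.path(dir, "fx"); out <- file.path(dir, "out")
make_fixture("perimeter_day", dir = fxd, seed = 1)
hab <- rect_polygon(33.5, 12.2)
write.csv(data.frame(x_m = hab[, 1], y_m = hab[, 2]),
          file.path(fxd, "habitat.csv"), row.names = FALSE)
jsonlite::write_json(list(detections_path = "detections.csv",
                          camera_left_path = "camera_left.json",
                          camera_right_path = "camera_right.json",
                          habitat_path = "habitat.csv",
                          schedule_path = "schedule.csv", seed = 1),
                     file.path(fxd, "config.json"), auto_unbox = TRUE)
cfg <- read_pipeline_config(file.path(fxd, "config.json"))
run_pipeline(cfg, out, stages = c("mesh", "track", "stats"))
summarize_pipeline(out)
```

which prints (abridged):

```
== Block summary ==
block  type        n   speed(m/s)    yaw_rate(deg/s)       static      dynamic
ITS1   ITS     10270        0.200              1.572        0.951        0.049
ITS2   ITS      8772        0.696             -7.057        0.501        0.499
OTS1   OTS     13073        1.102             -7.935        0.021        0.980
OTS3   OTS     13235        1.211             -8.725        0.011        0.989
...
== Joint differential entropy (speed, yaw) ==
ITS1   ITS       1.012
ITS2   ITS       1.307
OTS1   OTS       0.258
OTS2   OTS       1.505
...
== Kolmogorov-Smirnov comparisons ==
speed        OTS1   OTS2        0.458          0     *
speed        OTS3   OTS5        0.026    0.00198
...
```

Reading it: the stationing-heavy ITS blocks (1 and 3) are ~95% static
with block-mean speeds around 0.2 m/s, while free-swimming OTS blocks
are >97% dynamic at 1.1–1.2 m/s apparent speed. Joint entropy separates
low-diversity steady perimeter swimming (OTS1, 0.26 nats) from
high-diversity mixed behavior (OTS2, 1.51 nats), and the K-S table
flags distribution differences between blocks of the same type (`*` =
significant at α = 0.001): blocks generated with the same behavior mix
(e.g. OTS3 vs OTS5 speed, Δ = 0.026) sit far below cross-mix
comparisons (OTS1 vs OTS2, Δ = 0.458).

A shell front end with the same stages is installed at
`inst/exec/podtrack` (`podtrack simulate|mesh|track|map|stats|run|report`).

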