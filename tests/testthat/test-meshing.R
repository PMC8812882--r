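test_that("confidence filtering keeps the inclusive boundary and is monotone", {
  d <- data.frame(confidence = c(0.94, 0.95, 0.99))
  expect_equal(nrow(filter_by_confidence(d, 0.95)), 2)
  expect_equal(nrow(filter_by_confidence(d, 0)), 3)
  expect_equal(nrow(filter_by_confidence(d, 1.0)), 0)
  counts <- vapply(seq(0, 1, 0.05), function(th) nrow(filter_by_confidence(d, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("drain filtering only touches detections inside configured regions", {
  mkdet <- function(cx, cy, id) data.frame(
    t_s = 0, camera_id = "left",
    x1 = cx - 10, y1 = cy - 10, x2 = cx + 10, y2 = cy - 10,
    x3 = cx + 10, y3 = cy + 10, x4 = cx - 10, y4 = cy + 10,
    confidence = 0.99, detection_id = id)
  region <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2, byrow = TRUE)
  always_drain <- function(d) rep(TRUE, nrow(d))
  regs <- list(drain_region("left", region, always_drain))
  outside <- mkdet(500, 500, 1)
  inside <- mkdet(50, 50, 2)
  expect_equal(nrow(filter_drain_false_positives(outside, regs)), 1)
  expect_equal(nrow(filter_drain_false_positives(inside, regs)), 0)
  # missing classifier is a configuration error
  expect_error(filter_drain_false_positives(inside, list(drain_region("left", region))),
               "classifier")
})

test_that("planted drain artifacts are removed exactly by the oracle classifier", {
  set.seed(21)
  rig <- default_rig()
  cfg <- scenario_config(n_animals = 3, duration = 30, seed = 5)
  tracks <- simulate_tracks(cfg)
  sens <- sensor_model(rig, drain_world = list(left = list(c(6, 3)), right = list(c(28, 4))),
                       drain_rate = 120)
  rd <- render_detections(tracks, sens, seed = 6)
  n_drain <- sum(rd$truth$is_drain)
  expect_gt(n_drain, 20)
  # image-space drain regions: project a window around each site
  reg_for <- function(cid, site) {
    wq <- rbind(site + c(-1, -1), site + c(1, -1), site + c(1, 1), site + c(-1, 1))
    drain_region(cid, project_points(rig[[cid]]$H_inv, wq),
                 drain_classifier_oracle(rd$truth$detection_id[rd$truth$is_drain]))
  }
  filtered <- filter_drain_false_positives(rd$detections,
                                           list(reg_for("left", c(6, 3)), reg_for("right", c(28, 4))))
  expect_equal(nrow(rd$detections) - nrow(filtered), n_drain)
  expect_false(any(filtered$detection_id %in% rd$truth$detection_id[rd$truth$is_drain]))
})

test_that("polygon IoU matches closed forms and is symmetric", {
  sq <- function(x0, y0, s = 1) matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
                                       ncol = 2, byrow = TRUE)
  expect_equal(polygon_iou(sq(0, 0), sq(0, 0)), 1.0)
  expect_equal(polygon_iou(sq(0, 0), sq(5, 5)), 0.0)
  expect_equal(polygon_iou(sq(0, 0), sq(0.5, 0)), 1 / 3, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:20) {
    a <- sq(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.5, 2))
    b <- sq(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.5, 2))
    expect_equal(polygon_iou(a, b), polygon_iou(b, a), tolerance = 1e-12)
  }
  expect_error(polygon_iou(sq(0, 0, 0), sq(0, 0)), "zero-area")
})

test_that("mutual-best association pairs boxes correctly", {
  sq <- function(x0, y0, s = 1) matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
                                       ncol = 2, byrow = TRUE)
  # one overlapping pair
  a <- associate_mutual_best(list(sq(0, 0)), list(sq(0.3, 0)))
  expect_equal(nrow(a$pairs), 1)
  # L1 overlaps R1 (high) and R2 (low): L1-R1 paired, R2 passes through
  a <- associate_mutual_best(list(sq(0, 0)), list(sq(0.3, 0), sq(0.8, 0)))
  expect_equal(a$pairs$right, 1)
  expect_false(a$right_matched[2])
  # verify against exhaustive enumeration of the IoU matrix
  iou <- outer(1, 1:2, Vectorize(function(i, j)
    polygon_iou(sq(0, 0), list(sq(0.3, 0), sq(0.8, 0))[[j]])))
  expect_equal(a$pairs$iou, max(iou))
  # disjoint boxes: nothing pairs
  a <- associate_mutual_best(list(sq(0, 0)), list(sq(10, 10)))
  expect_equal(nrow(a$pairs), 0)
  expect_false(any(a$left_matched))
  # symmetry under role swap
  L <- list(sq(0, 0), sq(3, 0)); R <- list(sq(0.2, 0), sq(3.4, 0))
  a1 <- associate_mutual_best(L, R)$pairs
  a2 <- associate_mutual_best(R, L)$pairs
  expect_equal(a1[order(a1$left), c("iou")], a2[order(a2$right), c("iou")])
})

test_that("mesh weights follow the distance law w_n = d_b / (2 d_l)", {
  rig <- default_rig()
  ov <- rig$overlap
  # exactly on the midline: equal weights
  w <- mesh_weights(c(ov$l_s, 6.1), ov, rig$left, rig$right)
  expect_equal(w$w_n, 0.5)
  expect_equal(w$w_n + w$w_f, 1)
  # on a boundary: all weight to the far camera
  y <- 6.1
  bl <- fov_boundary_x_at(rig$left, y)
  w <- mesh_weights(c(bl, y), ov, rig$left, rig$right)
  expect_equal(w$w_n, 0, tolerance = 1e-9)
  expect_equal(w$w_f, 1, tolerance = 1e-9)
  # substitution d_b = 0.5 d_l -> w_n = 0.25
  b_n <- fov_boundary_x_at(rig$right, y)
  d_l <- abs(ov$l_s - b_n)
  u <- c(b_n + 0.5 * d_l, y)
  w <- mesh_weights(u, ov, rig$left, rig$right)
  expect_equal(w$w_n, 0.25, tolerance = 1e-9)
  expect_equal(w$near, "right")
})

test_that("weight partition and monotonicity hold across the strip", {
  rig <- default_rig()
  ov <- rig$overlap
  set.seed(23)
  y <- 6.0
  b_n <- fov_boundary_x_at(rig$right, y)
  xs <- seq(b_n + 1e-6, ov$l_s, length.out = 50)
  ws <- vapply(xs, function(x) mesh_weights(c(x, y), ov, rig$left, rig$right)$w_n,
               numeric(1))
  expect_true(all(diff(ws) > 0))          # increases from boundary to midline
  expect_equal(ws[length(ws)], 0.5)
  for (i in 1:200) {
    u <- c(runif(1, ov$strip[1], ov$strip[2]), runif(1, 0.5, 11.7))
    w <- mesh_weights(u, ov, rig$left, rig$right)
    expect_equal(w$w_n + w$w_f, 1)
    expect_true(w$w_n >= 0 && w$w_n <= 0.5)
    expect_equal(w$w_n, min(w$d_b / (2 * w$d_l), 0.5), tolerance = 1e-12)
  }
})

test_that("meshing is idempotent for identical boxes and conserves detection counts", {
  rig <- default_rig()
  ov <- rig$overlap
  # the same world box reported by both cameras meshes to its centroid
  ctr <- c(ov$l_s - 0.7, 6.2)
  hx <- 1.1; hy <- 0.5
  wq <- rbind(ctr + c(-hx, -hy), ctr + c(hx, -hy), ctr + c(hx, hy), ctr + c(-hx, hy))
  mkrow <- function(cam, id) {
    q <- project_points(cam$H_inv, wq)
    data.frame(t_s = 0, camera_id = cam$camera_id,
               x1 = q[1, 1], y1 = q[1, 2], x2 = q[2, 1], y2 = q[2, 2],
               x3 = q[3, 1], y3 = q[3, 2], x4 = q[4, 1], y4 = q[4, 2],
               confidence = 0.99, detection_id = id)
  }
  m <- mesh_simple(rbind(mkrow(rig$left, 1), mkrow(rig$right, 2)))
  expect_equal(nrow(m), 1)
  expect_equal(m$n_sources, 2)
  expect_equal(c(m$u_x, m$u_y), ctr, tolerance = 1e-6)

  # conservation: |meshed| = |lefts| + |rights| - |pairs| on a synthetic frame
  set.seed(24)
  cfg <- scenario_config(n_animals = 5, duration = 10, seed = 9)
  rd <- render_detections(simulate_tracks(cfg), sensor_model(rig, dropout = 0), seed = 10)
  m <- mesh_simple(rd$detections)
  n_pairs <- sum(m$n_sources == 2)
  n_kept <- sum(rd$detections$confidence >= 0.95)   # confidence gate applies first
  expect_equal(nrow(m), n_kept - n_pairs)
})

test_that("detection tables round-trip through both reader dialects", {
  det <- line_stream(0:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(det, path, row.names = FALSE)
  back <- read_detections(path)
  expect_equal(back$t, det$t_s)
  expect_equal(back$x3, det$x3)
  # xywh dialect
  d2 <- data.frame(t_s = c(0, 0.1), camera_id = "left", x = c(10, 20), y = c(5, 6),
                   w = 40, h = 30, confidence = 0.99)
  write.csv(d2, path, row.names = FALSE)
  back2 <- read_detections(path)
  expect_equal(back2$x2, d2$x + d2$w)
  expect_equal(back2$y4, d2$y + d2$h)
})
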