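test_that("minor-axis kernel has the right scale and normalization", {
  D1 <- minor_axis_kernel(0.2, 20)
  expect_equal(sum(D1), 1)
  expect_equal(length(D1) %% 2, 1)
  ctr <- (length(D1) + 1) / 2
  sd_px <- sqrt(sum(D1 * (seq_along(D1) - ctr)^2))
  expect_equal(sd_px, 4, tolerance = 0.01)   # 0.2 m at 20 px/m
  # unit case matches the direct sampled-Gaussian formula
  D <- minor_axis_kernel(1, 1)
  x <- -4:4
  expect_equal(D, dnorm(x) / sum(dnorm(x)))
})

test_that("depth error geometry follows the similar-triangles pinhole rule", {
  rig <- default_rig()
  cam <- rig$left
  # at the nadir the error vanishes
  g0 <- depth_error_geometry(cam$world_position, cam, max_depth = 7, s = 20)
  expect_equal(g0$e_m, 0)
  # substitution: h_c = 7, depth 7, r = 2, s = 20 -> 40 px
  u <- cam$world_position + c(2, 0)
  g <- depth_error_geometry(u, cam, max_depth = 7, s = 20)
  expect_equal(g$e_m, 40, tolerance = 1e-9)
  # direction points from the nadir toward the detection
  set.seed(41)
  for (i in 1:20) {
    u <- cam$world_position + runif(2, -5, 5)
    g <- depth_error_geometry(u, cam)
    d <- u - cam$world_position
    expect_equal(c(cos(g$psi_m), sin(g$psi_m)), d / sqrt(sum(d^2)), tolerance = 1e-12)
  }
})

test_that("error truncation stops exactly at the habitat wall", {
  poly <- habitat_rect()
  rig <- default_rig()
  # pointed straight at the wall from 1 m away: 3 m error -> 1 m (20 px)
  g <- structure(list(e_m = 3 * 20, psi_m = 0, s = 20, truncated = FALSE),
                 class = "error_geometry")
  gt <- truncate_error(g, poly, c(32.5, 6))
  expect_equal(gt$e_m, 20, tolerance = 1e-3)
  expect_true(gt$truncated)
  # already inside: unchanged
  g2 <- structure(list(e_m = 10, psi_m = 0, s = 20, truncated = FALSE),
                  class = "error_geometry")
  expect_equal(truncate_error(g2, poly, c(5, 6)), g2)
  # randomized: truncated endpoint inside, one pixel further is outside
  set.seed(42)
  for (i in 1:50) {
    p <- c(runif(1, 0.5, 33), runif(1, 0.5, 11.7))
    g <- structure(list(e_m = runif(1, 10, 300), psi_m = runif(1, -pi, pi),
                        s = 20, truncated = FALSE), class = "error_geometry")
    gt <- truncate_error(g, poly, p)
    dirv <- c(cos(gt$psi_m), sin(gt$psi_m))
    expect_true(in_polygon(poly, p + (gt$e_m / 20) * dirv) ||
                  gt$e_m == 0)
    if (gt$truncated)
      expect_false(in_polygon(poly, p + ((gt$e_m + 1) / 20) * dirv))
  }
})

test_that("major-axis PDF matches delta and double-sum convolution oracles", {
  D1 <- minor_axis_kernel(0.2, 20)
  # near-delta minor kernel: D2 is approximately the resampled depth PDF
  tiny <- minor_axis_kernel(0.01, 20)
  uni <- structure(list(depth = seq(0, 7, length.out = 64),
                        density = rep(1 / 64, 64), max_depth = 7, mean_depth = 3.5),
                   class = "depth_pdf")
  D2 <- major_axis_pdf(uni, tiny, 40)
  core <- D2[(length(tiny) %/% 2 + 2):(length(D2) - length(tiny) %/% 2 - 1)]
  expect_lt(diff(range(core)) / mean(core), 1e-6)   # flat over the interior
  # delta depth PDF: D2 is a copy of D1
  delta <- structure(list(depth = c(0, 7), density = c(1, 0), max_depth = 7,
                          mean_depth = 0.1), class = "depth_pdf")
  D2d <- major_axis_pdf(delta, D1, 2)
  expect_equal(max(abs(D2d[seq_along(D1)] - D1)), 0, tolerance = 1e-9)
  # arbitrary PDF equals the O(n^2) convolution oracle
  dp <- depth_pdf()
  e_m <- 55
  D2a <- major_axis_pdf(dp, D1, e_m)
  g <- seq(0, 1, length.out = length(dp$density))
  a <- approx(g, dp$density, seq(0, 1, length.out = e_m))$y
  a <- a / sum(a)
  n <- length(a) + length(D1) - 1
  oracle <- numeric(n)
  for (i in seq_along(a)) for (j in seq_along(D1))
    oracle[i + j - 1] <- oracle[i + j - 1] + a[i] * D1[j]
  expect_equal(D2a, oracle / sum(oracle), tolerance = 1e-12)
  # degenerate path: no depth extent returns the pure camera kernel
  expect_equal(major_axis_pdf(dp, D1, 0), D1)
})

test_that("kernel rotation conserves mass and turns the major axis correctly", {
  D1 <- minor_axis_kernel(0.2, 20)
  dp <- depth_pdf()
  D2 <- major_axis_pdf(dp, D1, 60)
  k0 <- build_kernel(D1, D2, 0)
  expect_equal(k0$F, k0$E)
  expect_equal(sum(k0$F), 1, tolerance = 1e-9)
  # quarter turn transposes the kernel (up to interpolation and canvas pad)
  k90 <- build_kernel(D1, D2, pi / 2)
  expect_equal(sum(k90$F), 1, tolerance = 1e-9)
  moments <- function(F_) {
    r <- row(F_); c <- col(F_); w <- F_
    mx <- sum(w * c); my <- sum(w * r)
    matrix(c(sum(w * (c - mx)^2), sum(w * (c - mx) * (r - my)),
             sum(w * (c - mx) * (r - my)), sum(w * (r - my)^2)), 2)
  }
  m0 <- moments(k0$F); m90 <- moments(k90$F)
  expect_equal(m90[1, 1], m0[2, 2], tolerance = 0.02 * m0[1, 1])
  expect_equal(m90[2, 2], m0[1, 1], tolerance = 0.02 * m0[1, 1])
  # 30 degrees: principal axis of the second-moment tensor at 30 +/- 1 deg
  k30 <- build_kernel(D1, D2, 30 * pi / 180)
  expect_equal(sum(k30$F), 1, tolerance = 1e-9)
  ev <- eigen(moments(k30$F))
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  expect_lt(min(abs(((ang - 30) %% 180)), abs(((ang - 30) %% 180) - 180)), 1)
  expect_true(all(k30$F >= 0))
})

test_that("injection deposits exactly the requested mass", {
  poly <- habitat_rect()
  maps <- habitat_maps(poly, 20)
  D1 <- minor_axis_kernel(0.2, 20)
  dp <- depth_pdf()
  # single unit injection
  g <- structure(list(e_m = 40, psi_m = 0.7, s = 20, truncated = FALSE),
                 class = "error_geometry")
  k <- build_kernel(D1, major_axis_pdf(dp, D1, 40), 0.7)
  M <- inject(maps$M, k$F, c(10, 6), g, 20)
  expect_equal(sum(M), 1, tolerance = 1e-9)
  # zero error: centered at p itself
  g0 <- structure(list(e_m = 0, psi_m = 0, s = 20, truncated = FALSE),
                  class = "error_geometry")
  k0 <- build_kernel(D1, D1, 0)
  # p at the centre of pixel (col 201, row 121)
  M0 <- inject(matrix(0, 244, 670), k0$F, c(10.025, 6.025), g0, 20)
  pk <- which(M0 == max(M0), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(121, 201))
  # mass-conservation sweep with random kernels, including near-edge clips
  set.seed(43)
  M <- maps$M
  n <- 1000
  for (i in 1:n) {
    p <- c(runif(1, 0.2, 33.3), runif(1, 0.2, 12))
    gi <- structure(list(e_m = runif(1, 0, 60), psi_m = runif(1, -pi, pi),
                         s = 20, truncated = FALSE), class = "error_geometry")
    ki <- build_kernel(D1, major_axis_pdf(dp, D1, gi$e_m), gi$psi_m)
    M <- inject(M, ki$F, p, gi, 20)
  }
  expect_equal(sum(M), n, tolerance = 1e-6 * n)
})

test_that("accumulated maps match a dense per-pixel oracle and satisfy map algebra", {
  set.seed(44)
  rig <- default_rig()
  poly <- habitat_rect()
  dp <- depth_pdf()
  n <- 60
  det <- data.frame(u_x = runif(n, 1, 32.5), u_y = runif(n, 1, 11.5),
                    near_camera = sample(c("left", "right"), n, replace = TRUE),
                    speed = runif(n, 0.2, 2.5), yaw = runif(n, -pi, pi))
  det$speed[1:5] <- NA   # some detections without kinematics
  maps <- accumulate_maps(det, rig, poly, dp)
  expect_equal(sum(maps$M), n, tolerance = 1e-6 * n)
  oracle <- accumulate_oracle(det, rig, poly, dp)
  expect_equal(maps$M, oracle$M, tolerance = 1e-9)
  expect_equal(maps$N, oracle$N, tolerance = 1e-9)
  expect_equal(maps$Qx, oracle$Qx, tolerance = 1e-9)
  expect_equal(maps$Qy, oracle$Qy, tolerance = 1e-9)
  # S * M = N where defined; |(Qx, Qy)| <= N
  S <- speed_map(maps)
  def <- !is.na(S)
  expect_equal((S * maps$M)[def], maps$N[def], tolerance = 1e-9)
  expect_true(all(sqrt(maps$Qx^2 + maps$Qy^2) <= maps$N + 1e-9))
})

test_that("constant and mixed speeds produce the expected mean-speed map", {
  rig <- default_rig()
  poly <- habitat_rect()
  dp <- depth_pdf()
  det <- data.frame(u_x = rep(c(8, 25), each = 3), u_y = 6,
                    near_camera = rep(c("left", "right"), each = 3),
                    speed = 1.5, yaw = 0.3)
  maps <- accumulate_maps(det, rig, poly, dp)
  S <- speed_map(maps)
  expect_equal(range(S, na.rm = TRUE), c(1.5, 1.5), tolerance = 1e-9)
  # two co-located detections at speeds 1 and 3 average to 2
  det2 <- data.frame(u_x = c(10, 10), u_y = c(6, 6), near_camera = "left",
                     speed = c(1, 3), yaw = 0)
  S2 <- speed_map(accumulate_maps(det2, rig, poly, dp))
  expect_equal(range(S2, na.rm = TRUE), c(2, 2), tolerance = 1e-9)
})

test_that("subsampling conserves mass and commutes with the speed-map ratio", {
  set.seed(45)
  rig <- default_rig()
  poly <- habitat_rect()
  n <- 40
  det <- data.frame(u_x = runif(n, 1, 32.5), u_y = runif(n, 1, 11.5),
                    near_camera = "left", speed = runif(n, 0.3, 2),
                    yaw = runif(n, -pi, pi))
  maps <- accumulate_maps(det, rig, poly, depth_pdf())
  Msub <- subsample_map(maps$M, 20, 1)
  expect_equal(dim(Msub), c(13, 34))
  expect_equal(sum(Msub), sum(maps$M), tolerance = 1e-9)
  # uniform map: every coarse cell collects 400x the fine mass
  uni <- matrix(2, 240, 660)
  expect_true(all(subsample_map(uni, 20, 1) == 2 * 400))
  expect_error(subsample_map(uni, 20, 3), "integer|divisible")
  # occupancy-weighted S subsample identity
  Nsub <- subsample_map(maps$N, 20, 1)
  Ssub <- Nsub / Msub
  expect_equal(Ssub[Msub > 1e-12],
               (subsample_map(maps$N, 20, 1) / subsample_map(maps$M, 20, 1))[Msub > 1e-12])
})

test_that("maps round-trip through the TIFF + sidecar writer", {
  set.seed(46)
  rig <- default_rig()
  det <- data.frame(u_x = runif(10, 2, 30), u_y = runif(10, 2, 10),
                    near_camera = "left", speed = runif(10, 0.3, 2), yaw = 0.5)
  maps <- accumulate_maps(det, rig, habitat_rect(), depth_pdf())
  dir <- withr::local_tempdir()
  write_maps(maps, dir, "all")
  back <- read_maps(dir, "all")
  expect_equal(back$M, maps$M, tolerance = 1e-6)
  expect_equal(back$Qy, maps$Qy, tolerance = 1e-6)
  expect_equal(back$s, maps$s)
})
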