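# Shared fixtures and independent oracles for the test suite.

# cached default camera rig (DLT runs once per test session)
default_rig <- local({
  rig <- NULL
  function() {
    if (is.null(rig)) rig <<- make_default_cameras()
    rig
  }
})

habitat_rect <- function() rect_polygon(33.5, 12.2)

# a well-conditioned random projective homography (mild perspective)
random_homography <- function() {
  matrix(c(runif(1, 0.8, 1.5), runif(1, -0.2, 0.2), runif(1, -10, 10),
           runif(1, -0.2, 0.2), runif(1, 0.8, 1.5), runif(1, -10, 10),
           runif(1, -2e-4, 2e-4), runif(1, -2e-4, 2e-4), 1),
         3, 3, byrow = TRUE)
}

# brute-force two-sample K-S distance: scan |ECDF_a - ECDF_b| at every
# pooled point
ks_bruteforce <- function(a, b) {
  z <- c(a, b)
  d <- 0
  for (x in z) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# dense independent accumulation oracle for the habitat maps: places each
# detection's kernel into full-size maps with plain index arithmetic
# (no caching, no clip-renormalize sharing with inject())
accumulate_oracle <- function(det, cameras, poly, depth, s = 20, sigma_m = 0.2) {
  nx <- ceiling(max(poly[, 1])) * s; ny <- ceiling(max(poly[, 2])) * s
  M <- N <- Qx <- Qy <- matrix(0, ny, nx)
  D1 <- minor_axis_kernel(sigma_m, s)
  place <- function(map, F_, cx, cy, val) {
    rr <- round(cy * s + 0.5 - (nrow(F_) + 1) / 2) + seq_len(nrow(F_))
    cc <- round(cx * s + 0.5 - (ncol(F_) + 1) / 2) + seq_len(ncol(F_))
    ok_r <- rr >= 1 & rr <= ny; ok_c <- cc >= 1 & cc <= nx
    Fc <- F_[ok_r, ok_c, drop = FALSE]
    map[rr[ok_r], cc[ok_c]] <- map[rr[ok_r], cc[ok_c]] + Fc * (val / sum(Fc))
    map
  }
  for (i in seq_len(nrow(det))) {
    p <- c(det$u_x[i], det$u_y[i])
    g <- depth_error_geometry(p, cameras[[det$near_camera[i]]],
                              max_depth = depth$max_depth, s = s)
    g <- truncate_error(g, poly, p)
    ker <- build_kernel(D1, major_axis_pdf(depth, D1, g$e_m), g$psi_m)
    cx <- p[1] + 0.5 * (g$e_m / s) * cos(g$psi_m)
    cy <- p[2] + 0.5 * (g$e_m / s) * sin(g$psi_m)
    M <- place(M, ker$F, cx, cy, 1)
    if (!is.na(det$speed[i])) {
      N <- place(N, ker$F, cx, cy, det$speed[i])
      Qx <- place(Qx, ker$F, cx, cy, det$speed[i] * cos(det$yaw[i]))
      Qy <- place(Qy, ker$F, cx, cy, det$speed[i] * sin(det$yaw[i]))
    }
  }
  list(M = M, N = N, Qx = Qx, Qy = Qy)
}

# single-camera noise-free detection stream along a straight path
line_stream <- function(frames, drop_frames = integer(0), x0 = 2, y0 = 6, vx = 1) {
  podtrack:::straight_line_detections(default_rig()$left, x0, y0, vx, frames,
                                      drop_frames = drop_frames)
}

mesh_simple <- function(det) {
  rig <- default_rig()
  mesh_detections(det, rig$left, rig$right, rig$overlap, habitat_rect())
}
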