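# Synthetic habitat: ground-truth multi-animal trajectories and noisy
# two-camera detection streams with the statistical structure the pipeline
# assumes (smooth 10 Hz tracks, detection noise, dropouts, drain false
# positives, unobserved depth).

#' Scenario configuration for the trajectory simulator
#'
#' @param n_animals number of animals, default 7.
#' @param duration scenario length (s).
#' @param rate_hz frame rate, default 10.
#' @param habitat_polygon perimeter, default the 33.5 x 12.2 m rectangle.
#' @param mode_schedule data frame \code{start_s, end_s, mode, speed} with
#'   mode one of "perimeter", "stationing", "mixed"; \code{speed} is the
#'   commanded cruise speed (m/s) for swimming segments. Default: a single
#'   perimeter-loop segment at 1.4 m/s spanning the duration.
#' @param depth a \code{\link{depth_pdf}} governing dive depths.
#' @param island stationing focus point (m), default near the central
#'   island edge.
#' @param a_max acceleration bound (m/s^2), default 3.
#' @param chirality "cw" or "ccw" perimeter loop direction, default "cw".
#' @param seed integer RNG seed.
#' @return List of class \code{scenario_config}.
#' @export
scenario_config <- function(n_animals = 7L, duration = 300, rate_hz = 10,
                            habitat_polygon = rect_polygon(33.5, 12.2),
                            mode_schedule = NULL, depth = depth_pdf(),
                            island = c(16.75, 10.5), a_max = 3,
                            chirality = "cw", seed = 1L) {
  stopifnot(n_animals >= 1, duration > 0, rate_hz > 0)
  if (is.null(mode_schedule))
    mode_schedule <- data.frame(start_s = 0, end_s = duration,
                                mode = "perimeter", speed = 1.4)
  stopifnot(all(mode_schedule$mode %in% c("perimeter", "stationing", "mixed")))
  structure(list(n_animals = as.integer(n_animals), duration = duration,
                 rate_hz = rate_hz, habitat_polygon = habitat_polygon,
                 mode_schedule = mode_schedule, depth = depth, island = island,
                 a_max = a_max, chirality = chirality, seed = as.integer(seed)),
            class = "scenario_config")
}

inset_rect_waypoints <- function(poly, margin = 2.5) {
  xs <- range(poly[, 1]); ys <- range(poly[, 2])
  matrix(c(xs[1] + margin, ys[1] + margin,
           xs[2] - margin, ys[1] + margin,
           xs[2] - margin, ys[2] - margin,
           xs[1] + margin, ys[2] - margin),
         ncol = 2, byrow = TRUE)
}

#' Simulate ground-truth animal trajectories
#'
#' Mode-dependent waypoint/station controllers produce smooth trajectories
#' at the frame rate: \emph{perimeter} mode follows an inset loop of the
#' habitat edge (commanded cruise speed, bounded yaw rate, chirality per
#' config); \emph{stationing} holds position near the island point with
#' slow Ornstein-Uhlenbeck jitter (speeds below the 0.5 m/s static
#' threshold); \emph{mixed} switches between the two per animal with a
#' Markov chain (mean dwell ~20 s). Speed changes are limited by
#' \code{a_max}; a wall-repulsion term keeps tracks inside the perimeter.
#' Depth targets are redrawn from the depth distribution on a slow
#' timescale and approached smoothly. Deterministic for a given seed.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return Data frame of class \code{ground_truth_tracks}: \code{animal,
#'   t, x, y, depth, v_x, v_y, speed, mode}.
#' @export
simulate_tracks <- function(config) {
  sched <- config$mode_schedule
  if (any(sched$speed > 0.95 * config$a_max * 10))
    stop("simulate_tracks: commanded speed unreachable under the acceleration bound")
  withr::with_seed(config$seed, {
    dt <- 1 / config$rate_hz
    nt <- round(config$duration * config$rate_hz)
    poly <- config$habitat_polygon
    wp_all <- inset_rect_waypoints(poly)
    depth_cdf <- cumsum(config$depth$density)
    draw_depth <- function() {
      u <- runif(1)
      config$depth$depth[which.max(depth_cdf >= u)]
    }
    out <- vector("list", config$n_animals)
    for (a in seq_len(config$n_animals)) {
      cw <- config$chirality == "cw"
      wp <- if (cw) wp_all[c(4, 3, 2, 1), ] else wp_all
      wp_i <- sample(4, 1)
      pos <- wp[wp_i, ] + runif(2, -1, 1)
      heading <- runif(1, -pi, pi)
      speed <- 0
      depth_now <- draw_depth(); depth_target <- depth_now
      sub_mode <- "perimeter"   # state for mixed mode
      station <- config$island + runif(2, -1.5, 1.5)
      M <- matrix(NA_real_, nt, 8)
      mode_lab <- character(nt)
      for (i in seq_len(nt)) {
        t <- (i - 1) * dt
        seg <- sched[sched$start_s <= t & t < sched$end_s, , drop = FALSE]
        if (!nrow(seg)) seg <- sched[nrow(sched), , drop = FALSE]
        mode <- seg$mode[1]; cruise <- seg$speed[1]
        if (mode == "mixed") {
          # Markov switching, mean dwell 20 s
          if (runif(1) < dt / 20) sub_mode <- if (sub_mode == "perimeter") "stationing" else "perimeter"
          mode_eff <- sub_mode
        } else mode_eff <- mode
        if (mode_eff == "perimeter") {
          tgt <- wp[wp_i, ]
          if (sqrt(sum((pos - tgt)^2)) < 2) {
            wp_i <- if (wp_i == 4) 1 else wp_i + 1
            tgt <- wp[wp_i, ]
          }
          des_head <- atan2(tgt[2] - pos[2], tgt[1] - pos[1])
          des_speed <- cruise
          max_yaw_rate <- 1.2
        } else {
          err <- station - pos
          des_head <- atan2(err[2], err[1])
          des_speed <- min(0.35, 0.25 * sqrt(sum(err^2)))
          max_yaw_rate <- 2.5
          if (runif(1) < dt / 15) station <- config$island + runif(2, -1.5, 1.5)
        }
        # wall repulsion: steer toward the interior when close to the edge
        margin <- 1.0
        cl <- clamp_to_polygon(poly, pos)
        bd <- sqrt(sum((pos - cl)^2))  # 0 when inside
        near_wall <- FALSE
        xs <- range(poly[, 1]); ys <- range(poly[, 2])
        dwall <- min(pos[1] - xs[1], xs[2] - pos[1], pos[2] - ys[1], ys[2] - pos[2])
        if (dwall < margin && mode_eff == "perimeter") {
          ctr <- c(mean(xs), mean(ys))
          away <- atan2(ctr[2] - pos[2], ctr[1] - pos[1])
          # blend desired heading toward the interior
          w <- 1 - dwall / margin
          des_head <- atan2((1 - w) * sin(des_head) + w * sin(away),
                            (1 - w) * cos(des_head) + w * cos(away))
          near_wall <- TRUE
        }
        dh <- wrap_angle(des_head - heading)
        heading <- heading + sign(dh) * min(abs(dh), max_yaw_rate * dt) +
          rnorm(1, 0, 0.02)
        dv <- des_speed - speed
        speed <- speed + sign(dv) * min(abs(dv), config$a_max * dt) +
          rnorm(1, 0, 0.01)
        speed <- max(speed, 0)
        vel <- speed * c(cos(heading), sin(heading))
        pos <- pos + vel * dt
        newp <- clamp_to_polygon(poly, pos)
        if (any(newp != pos)) pos <- newp
        if (runif(1) < dt / 10) depth_target <- draw_depth()
        dd <- depth_target - depth_now
        depth_now <- depth_now + sign(dd) * min(abs(dd), 1.0 * dt)
        M[i, ] <- c(a, t, pos, depth_now, vel, speed)
        mode_lab[i] <- mode_eff
      }
      out[[a]] <- data.frame(animal = M[, 1], t = M[, 2], x = M[, 3], y = M[, 4],
                             depth = M[, 5], v_x = M[, 6], v_y = M[, 7],
                             speed = M[, 8], mode = mode_lab)
    }
    res <- do.call(rbind, out)
    class(res) <- c("ground_truth_tracks", "data.frame")
    res
  })
}

#' Default dual-camera rig for the synthetic habitat
#'
#' Two overhead cameras 2 m apart above the habitat centre (heights 7 m),
#' each covering slightly more than half of the 33.5 x 12.2 m area with a
#' mild keystone so the projected borders are not perfectly vertical.
#' Calibration correspondences are generated from the ground-truth world
#' quads and passed through the normalized DLT, exactly as for a real rig.
#'
#' @param image_size synthetic sensor size (px), default c(1380, 1035).
#' @return List with \code{left}, \code{right} camera models and
#'   \code{overlap}.
#' @export
make_default_cameras <- function(image_size = c(1380, 1035)) {
  w <- image_size[1]; h <- image_size[2]
  corners_px <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
  # world quads seen by each sensor (slight keystone on the overlap edge)
  left_world <- matrix(c(-0.1, -0.1,
                         18.6, 0.15,
                         18.4, 12.1,
                         -0.15, 12.3), ncol = 2, byrow = TRUE)
  right_world <- matrix(c(14.9, 0.12,
                          33.6, -0.1,
                          33.65, 12.3,
                          15.1, 12.05), ncol = 2, byrow = TRUE)
  left <- camera_model("left", corners_px, left_world, image_size,
                       world_position = c(15.75, 6.1), height_above_water = 7)
  right <- camera_model("right", corners_px, right_world, image_size,
                        world_position = c(17.75, 6.1), height_above_water = 7)
  list(left = left, right = right, overlap = compute_overlap(left, right))
}

#' Sensor model for detection rendering
#'
#' @param cameras output of \code{\link{make_default_cameras}} (or a list
#'   with \code{left}, \code{right}, \code{overlap}).
#' @param noise_sigma world-frame detection noise sd (m), default 0.1.
#' @param dropout per-frame per-camera missed-detection probability,
#'   default 0.2.
#' @param box_size world-frame detection box side (m), default c(2.2, 1.0)
#'   (animal-length scale).
#' @param drain_world optional list per camera of world points where drain
#'   artifacts appear.
#' @param drain_rate drain false positives per minute per site, default 0.
#' @return List of class \code{sensor_model}.
#' @export
sensor_model <- function(cameras, noise_sigma = 0.1, dropout = 0.2,
                         box_size = c(2.2, 1.0), drain_world = NULL,
                         drain_rate = 0) {
  stopifnot(noise_sigma >= 0, dropout >= 0, dropout <= 1)
  structure(list(cameras = cameras, noise_sigma = noise_sigma,
                 dropout = dropout, box_size = box_size,
                 drain_world = drain_world, drain_rate = drain_rate),
            class = "sensor_model")
}

apparent_position <- function(p, depth, camera) {
  # pinhole: the surface point where the camera ray through the submerged
  # animal crosses the water plane
  c0 <- camera$world_position
  c0 + (p - c0) * camera$height_above_water / (camera$height_above_water + depth)
}

world_box_to_image <- function(center, box_size, H_inv) {
  hx <- box_size[1] / 2; hy <- box_size[2] / 2
  wq <- matrix(c(center[1] - hx, center[2] - hy,
                 center[1] + hx, center[2] - hy,
                 center[1] + hx, center[2] + hy,
                 center[1] - hx, center[2] + hy), ncol = 2, byrow = TRUE)
  project_points(H_inv, wq)
}

#' Render two-camera detection streams from ground-truth tracks
#'
#' For each frame, animal and camera with the animal in view, the apparent
#' surface position is displaced toward the camera nadir by the pinhole
#' depth effect, world-frame Gaussian noise is added, a box of
#' animal-length scale is emitted through the inverse homography, and the
#' detection is dropped with the dropout probability. Drain false
#' positives are injected as Poisson events at the configured sites. A
#' truth table links detection ids to animal ids.
#'
#' @param tracks \code{\link{simulate_tracks}} output.
#' @param sensors a \code{\link{sensor_model}}.
#' @param seed RNG seed for the sensor noise.
#' @return List with \code{detections} (raw detection table: \code{t_s,
#'   camera_id, x1..y4, confidence, detection_id}) and \code{truth}
#'   (\code{detection_id, animal, is_drain}).
#' @export
render_detections <- function(tracks, sensors, seed = 1L) {
  cams <- sensors$cameras
  hx <- sensors$box_size[1] / 2; hy <- sensors$box_size[2] / 2

  boxes_to_image <- function(cx, cy, H_inv) {
    # vectorized: 4 world corners per center, projected per corner set
    q <- list(project_points(H_inv, cbind(cx - hx, cy - hy)),
              project_points(H_inv, cbind(cx + hx, cy - hy)),
              project_points(H_inv, cbind(cx + hx, cy + hy)),
              project_points(H_inv, cbind(cx - hx, cy + hy)))
    cbind(q[[1]], q[[2]], q[[3]], q[[4]])
  }

  withr::with_seed(seed, {
    parts <- list(); tparts <- list(); det_id0 <- 0L
    for (cid in c("left", "right")) {
      cam <- cams[[cid]]
      h_c <- cam$height_above_water
      fac <- h_c / (h_c + tracks$depth)
      ax <- cam$world_position[1] + (tracks$x - cam$world_position[1]) * fac
      ay <- cam$world_position[2] + (tracks$y - cam$world_position[2]) * fac
      vis <- if (cid == "left") ax <= cam$fov_boundary_x else ax >= cam$fov_boundary_x
      keep <- which(vis & runif(nrow(tracks)) >= sensors$dropout)
      if (length(keep)) {
        n <- length(keep)
        nx <- ax[keep] + rnorm(n, 0, sensors$noise_sigma)
        ny <- ay[keep] + rnorm(n, 0, sensors$noise_sigma)
        conf <- ifelse(runif(n) < 0.05, runif(n, 0.5, 0.95), runif(n, 0.95, 1))
        q <- boxes_to_image(nx, ny, cam$H_inv)
        ids <- det_id0 + seq_len(n)
        parts[[length(parts) + 1L]] <- data.frame(
          t_s = tracks$t[keep], camera_id = cid,
          x1 = q[, 1], y1 = q[, 2], x2 = q[, 3], y2 = q[, 4],
          x3 = q[, 5], y3 = q[, 6], x4 = q[, 7], y4 = q[, 8],
          confidence = conf, detection_id = ids)
        tparts[[length(tparts) + 1L]] <- data.frame(
          detection_id = ids, animal = tracks$animal[keep], is_drain = FALSE)
        det_id0 <- det_id0 + n
      }
      if (!is.null(sensors$drain_world) && sensors$drain_rate > 0) {
        tgrid <- sort(unique(tracks$t))
        dt <- if (length(tgrid) > 1) tgrid[2] - tgrid[1] else 0.1
        for (site in sensors$drain_world[[cid]]) {
          nfp <- rpois(length(tgrid), sensors$drain_rate / 60 * dt)
          tt <- rep(tgrid, nfp)
          n <- length(tt)
          if (!n) next
          cx <- site[1] + rnorm(n, 0, 0.1); cy <- site[2] + rnorm(n, 0, 0.1)
          q <- boxes_to_image(cx, cy, cam$H_inv)
          ids <- det_id0 + seq_len(n)
          parts[[length(parts) + 1L]] <- data.frame(
            t_s = tt, camera_id = cid,
            x1 = q[, 1], y1 = q[, 2], x2 = q[, 3], y2 = q[, 4],
            x3 = q[, 5], y3 = q[, 6], x4 = q[, 7], y4 = q[, 8],
            confidence = runif(n, 0.95, 1), detection_id = ids)
          tparts[[length(tparts) + 1L]] <- data.frame(
            detection_id = ids, animal = NA_real_, is_drain = TRUE)
          det_id0 <- det_id0 + n
        }
      }
    }
    det <- do.call(rbind, parts)
    det <- det[order(det$t_s, det$camera_id, det$detection_id), ]
    rownames(det) <- NULL
    list(detections = det, truth = do.call(rbind, tparts))
  })
}
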