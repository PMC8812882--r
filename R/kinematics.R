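# Kinematic series derived from tracklets: speed, yaw, yaw rate, and the
# static/dynamic movement-state split.

#' Static/dynamic movement threshold (m/s)
#'
#' Animals travelling below 0.5 m/s (little to no active fluking) are
#' classified static; at or above, dynamic.
#' @export
STATIC_SPEED_THRESHOLD <- 0.5

#' Classify movement state from speed
#'
#' @param speed numeric vector of non-negative speeds (m/s).
#' @param threshold split point, default \code{\link{STATIC_SPEED_THRESHOLD}}.
#' @return Character vector, "static" (speed < threshold) or "dynamic"
#'   (speed >= threshold; the boundary value counts as dynamic, since
#'   static is defined by strictly "less than").
#' @export
classify_movement <- function(speed, threshold = STATIC_SPEED_THRESHOLD) {
  stopifnot(all(speed >= 0))
  ifelse(speed < threshold, "static", "dynamic")
}

wrap_angle <- function(a) {
  # into (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Derive the kinematic series of a tracklet
#'
#' Speed is the magnitude of the filtered velocity; yaw is
#' \code{atan2(v_y, v_x)} wrapped to (-pi, pi]; the yaw rate is the central
#' difference of the unwrapped yaw over two frame periods (one-sided at the
#' ends). Tracklets with fewer than 3 states are flagged unreliable and
#' return \code{NULL} so they are excluded from statistics.
#'
#' @param tracklet a \code{tracklet} (from \code{\link{track_detections}}).
#' @param dt frame period (s), default 0.1.
#' @return Data frame \code{k, t, speed, yaw, yaw_rate, movement_state,
#'   confirmed, detection_id}, or \code{NULL} for short tracklets.
#' @export
derive_kinematics <- function(tracklet, dt = 0.1) {
  st <- tracklet$states
  n <- nrow(st)
  if (n < 3) return(NULL)
  speed <- sqrt(st$v_x^2 + st$v_y^2)
  yaw_raw <- atan2(st$v_y, st$v_x)
  uw <- signal::unwrap(yaw_raw)
  yaw_rate <- numeric(n)
  yaw_rate[2:(n - 1)] <- (uw[3:n] - uw[1:(n - 2)]) / (2 * dt)
  yaw_rate[1] <- (uw[2] - uw[1]) / dt
  yaw_rate[n] <- (uw[n] - uw[n - 1]) / dt
  data.frame(k = tracklet$k, t = st$t, speed = speed, yaw = wrap_angle(yaw_raw),
             yaw_rate = yaw_rate, movement_state = classify_movement(speed),
             confirmed = st$confirmed, detection_id = st$detection_id)
}

#' Kinematics for every tracklet in a set
#'
#' @param tracklet_set a \code{tracklet_set}.
#' @param dt frame period (s); defaults to the tracker's.
#' @return Combined kinematics data frame; tracklets shorter than 3 states
#'   are skipped with a message.
#' @export
tracklet_kinematics <- function(tracklet_set, dt = tracklet_set$params$dt) {
  kin <- lapply(tracklet_set$tracklets, derive_kinematics, dt = dt)
  short <- sum(vapply(kin, is.null, logical(1)))
  if (short) message("tracklet_kinematics: ", short,
                     " tracklets shorter than 3 states excluded")
  out <- do.call(rbind, kin)
  if (is.null(out))
    out <- data.frame(k = integer(0), t = numeric(0), speed = numeric(0),
                      yaw = numeric(0), yaw_rate = numeric(0),
                      movement_state = character(0), confirmed = logical(0),
                      detection_id = integer(0))
  out
}

#' Rolling standard deviations of the kinematic metrics
#'
#' Centered rolling standard deviation per tracklet for speed, yaw
#' (unwrapped before differencing so the +/-pi seam does not inflate the
#' spread) and yaw rate. The default window is 2 s (21 steps at 10 Hz);
#' edges use the available support. Tracklets shorter than the window are
#' excluded.
#'
#' @param kinematics output of \code{\link{tracklet_kinematics}}.
#' @param window window length in steps (odd recommended), default 21.
#' @return Data frame \code{k, t, speed_sd, yaw_sd, yaw_rate_sd}.
#' @export
rolling_std_metrics <- function(kinematics, window = 21L) {
  stopifnot(window >= 3)
  parts <- lapply(split(kinematics, kinematics$k), function(g) {
    if (nrow(g) < window) return(NULL)
    uw <- signal::unwrap(g$yaw)
    data.frame(k = g$k, t = g$t,
               speed_sd = zoo::rollapply(g$speed, window, sd, partial = TRUE, align = "center"),
               yaw_sd = zoo::rollapply(uw, window, sd, partial = TRUE, align = "center"),
               yaw_rate_sd = zoo::rollapply(g$yaw_rate, window, sd, partial = TRUE, align = "center"))
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(k = integer(0), t = numeric(0), speed_sd = numeric(0),
                      yaw_sd = numeric(0), yaw_rate_sd = numeric(0))
  rownames(out) <- NULL
  out
}
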