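# Tracklet generation: constant-velocity Kalman filtering with proximity
# gating, gap bridging, miss-count deactivation and truncation.

#' Tracker parameters
#'
#' @param dt frame period (s), default 0.1 (10 Hz).
#' @param q white-acceleration process noise intensity (m^2 s^-3), default 0.5.
#' @param r position measurement noise variance (m^2), default 0.2^2 — the
#'   nominal detection error of the camera system.
#' @param gate_radius association gate around the predicted position (m),
#'   default 0.8.
#' @param max_misses consecutive unassociated frames before a tracklet is
#'   deactivated, default 5.
#' @param init_vel_var initial velocity variance for new tracklets
#'   (m^2 s^-2), default 4.
#' @return List of class \code{tracker_params}.
#' @export
tracker_params <- function(dt = 0.1, q = 0.5, r = 0.2^2, gate_radius = 0.8,
                           max_misses = 5L, init_vel_var = 4) {
  stopifnot(dt > 0, gate_radius > 0, max_misses >= 1)
  structure(list(dt = dt, q = q, r = r, gate_radius = gate_radius,
                 max_misses = as.integer(max_misses), init_vel_var = init_vel_var),
            class = "tracker_params")
}

# State order (p_x, p_y, v_x, v_y).
cv_transition <- function(dt) {
  F <- diag(4)
  F[1, 3] <- dt; F[2, 4] <- dt
  F
}

cv_process_noise <- function(q, dt) {
  # white-acceleration (discretized) noise, independent per axis
  q11 <- q * dt^4 / 4; q12 <- q * dt^3 / 2; q22 <- q * dt^2
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- Q[2, 2] <- q11
  Q[3, 3] <- Q[4, 4] <- q22
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- q12
  Q
}

#' Kalman prediction under the constant-velocity model
#'
#' Position advances by one frame of the current velocity; velocity is
#' unchanged; the covariance is propagated through the transition with
#' process noise.
#'
#' @param state list with \code{x} (length-4 state, order
#'   \code{p_x, p_y, v_x, v_y}) and \code{P} (4 x 4 covariance).
#' @param params \code{\link{tracker_params}}.
#' @return Predicted state (same structure).
#' @export
kalman_predict <- function(state, params) {
  F <- cv_transition(params$dt)
  list(x = as.vector(F %*% state$x),
       P = F %*% state$P %*% t(F) + cv_process_noise(params$q, params$dt))
}

#' Kalman measurement update with a position-only observation
#'
#' @param state predicted state (list \code{x}, \code{P}).
#' @param z length-2 measured position (m).
#' @param params \code{\link{tracker_params}}.
#' @return Updated state; the covariance is symmetrized, and clipped to
#'   positive semidefinite (with a warning) if numerical noise drives an
#'   eigenvalue negative.
#' @export
kalman_update <- function(state, z, params) {
  H <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0), 2, 4, byrow = TRUE)
  S <- H %*% state$P %*% t(H) + diag(params$r, 2)
  K <- state$P %*% t(H) %*% solve(S)
  x <- state$x + as.vector(K %*% (z - as.vector(H %*% state$x)))
  P <- (diag(4) - K %*% H) %*% state$P
  P <- (P + t(P)) / 2
  if (any(diag(P) < 0)) {
    warning("kalman_update: clipping non-PSD covariance")
    e <- eigen(P, symmetric = TRUE)
    P <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
  }
  list(x = x, P = P)
}

#' Gate detections and associate them to tracklet predictions
#'
#' Each active tracklet claims the closest detection within
#' \code{gate_radius} of its predicted position; each detection can be
#' assigned to at most one tracklet. Contention is resolved by the smaller
#' predicted-position distance, then by the lower tracklet id (greedy
#' nearest-pair assignment).
#'
#' @param predicted n x 2 matrix of predicted tracklet positions.
#' @param detections m x 2 matrix of detection positions at the new frame.
#' @param gate_radius gate radius (m).
#' @return List with \code{assignment} (length n, detection index or NA)
#'   and \code{unassigned} (indices of unclaimed detections).
#' @export
gate_and_associate <- function(predicted, detections, gate_radius) {
  n <- nrow(predicted); m <- nrow(detections)
  assignment <- rep(NA_integer_, n)
  if (n && m) {
    cand <- NULL
    for (i in seq_len(n)) {
      dd <- sqrt((detections[, 1] - predicted[i, 1])^2 +
                   (detections[, 2] - predicted[i, 2])^2)
      ok <- which(dd <= gate_radius)
      if (length(ok))
        cand <- rbind(cand, cbind(i, ok, dd[ok]))
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand[, 3], cand[, 1]), , drop = FALSE]
      used_d <- rep(FALSE, m)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (is.na(assignment[i]) && !used_d[j]) {
          assignment[i] <- j
          used_d[j] <- TRUE
        }
      }
    }
  }
  list(assignment = assignment,
       unassigned = setdiff(seq_len(m), assignment[!is.na(assignment)]))
}

new_track <- function(k, frame, z, det_id, params) {
  env <- new.env(parent = emptyenv())
  env$k <- k
  env$x <- c(z, 0, 0)
  env$P <- diag(c(params$r, params$r, params$init_vel_var, params$init_vel_var))
  env$misses <- 0L
  n0 <- 64L
  env$hist <- matrix(NA_real_, n0, 6)  # frame, px, py, vx, vy, confirmed
  env$det_ids <- rep(NA_integer_, n0)
  env$n <- 0L
  record_state(env, frame, TRUE, det_id)
  env
}

record_state <- function(tr, frame, confirmed, det_id = NA_integer_) {
  tr$n <- tr$n + 1L
  if (tr$n > nrow(tr$hist)) {
    tr$hist <- rbind(tr$hist, matrix(NA_real_, nrow(tr$hist), 6))
    tr$det_ids <- c(tr$det_ids, rep(NA_integer_, length(tr$det_ids)))
  }
  tr$hist[tr$n, ] <- c(frame, tr$x, as.numeric(confirmed))
  tr$det_ids[tr$n] <- det_id
}

finalize_track <- function(tr, dt, deactivated_misses = NA_integer_) {
  h <- tr$hist[seq_len(tr$n), , drop = FALSE]
  ids <- tr$det_ids[seq_len(tr$n)]
  conf <- which(h[, 6] == 1)
  if (!length(conf)) return(NULL)
  last <- max(conf)                     # truncate at the last confirmed state
  h <- h[seq_len(last), , drop = FALSE]
  states <- data.frame(t = h[, 1] * dt, p_x = h[, 2], p_y = h[, 3],
                       v_x = h[, 4], v_y = h[, 5], confirmed = h[, 6] == 1,
                       detection_id = ids[seq_len(last)])
  structure(list(k = tr$k, t_start = states$t[1], t_end = states$t[nrow(states)],
                 states = states, n_misses_at_deactivation = deactivated_misses),
            class = "tracklet")
}

#' @export
print.tracklet <- function(x, ...) {
  cat(sprintf("<tracklet %d> t = [%.1f, %.1f] s, %d states (%d confirmed)\n",
              x$k, x$t_start, x$t_end, nrow(x$states), sum(x$states$confirmed)))
  invisible(x)
}

#' Generate tracklets from meshed detections
#'
#' Iterates prediction and association over the 10 Hz frame grid: active
#' tracklets are predicted one frame ahead; detections within the gate are
#' associated and used as Kalman reference signals; unassociated tracklets
#' coast on the prediction and are deactivated after \code{max_misses}
#' consecutive misses, truncated at the last confirmed association.
#' Unclaimed detections seed new tracklets with zero initial velocity.
#'
#' @param meshed meshed detection data frame (\code{t, u_x, u_y}, optionally
#'   \code{detection_id}).
#' @param params \code{\link{tracker_params}}.
#' @param t_end optional end of the recording (s). Frames after the last
#'   detection still advance the filter, so tracklets left without
#'   detections are deactivated by the miss counter rather than by the end
#'   of the detection table.
#' @return Object of class \code{tracklet_set}: list of tracklets plus the
#'   parameters used.
#' @export
track_detections <- function(meshed, params = tracker_params(), t_end = NULL) {
  dt <- params$dt
  frames <- round(meshed$t / dt)
  if (max(abs(meshed$t - frames * dt)) > 1e-6)
    stop("track_detections: detection timestamps are not on the frame grid")
  det_id <- if ("detection_id" %in% names(meshed)) meshed$detection_id
            else seq_len(nrow(meshed))
  ord <- order(frames)
  frames <- frames[ord]
  px <- meshed$u_x[ord]; py <- meshed$u_y[ord]; det_id <- det_id[ord]

  Fm <- cv_transition(dt); tFm <- t(Fm)
  Qm <- cv_process_noise(params$q, dt)
  Rm <- diag(params$r, 2)
  active <- list()
  done <- list()
  next_k <- 1L
  f0 <- min(frames)
  f1 <- if (is.null(t_end)) max(frames) else max(max(frames), round(t_end / dt))
  idx <- 1L; nd <- length(frames)

  for (f in f0:f1) {
    zs <- NULL; zid <- NULL
    while (idx <= nd && frames[idx] == f) {
      zs <- rbind(zs, c(px[idx], py[idx])); zid <- c(zid, det_id[idx])
      idx <- idx + 1L
    }
    if (f > f0) {
      # predict all active tracklets (precomputed transition/noise matrices)
      for (tr in active) {
        tr$x <- as.vector(Fm %*% tr$x)
        tr$P <- Fm %*% tr$P %*% tFm + Qm
      }
      npred <- length(active)
      pred <- if (npred) t(vapply(active, function(tr) tr$x[1:2], numeric(2)))
              else matrix(numeric(0), ncol = 2)
      det <- if (is.null(zs)) matrix(numeric(0), ncol = 2) else zs
      assoc <- gate_and_associate(pred, det, params$gate_radius)
      keep <- logical(npred)
      for (i in seq_len(npred)) {
        tr <- active[[i]]
        j <- assoc$assignment[i]
        if (!is.na(j)) {
          # position-only measurement update
          S <- tr$P[1:2, 1:2] + Rm
          K <- tr$P[, 1:2] %*% solve(S)
          tr$x <- tr$x + as.vector(K %*% (det[j, ] - tr$x[1:2]))
          P <- tr$P - K %*% tr$P[1:2, ]
          tr$P <- (P + t(P)) / 2
          tr$misses <- 0L
          record_state(tr, f, TRUE, zid[j])
          keep[i] <- TRUE
        } else {
          tr$misses <- tr$misses + 1L
          record_state(tr, f, FALSE)
          if (tr$misses >= params$max_misses) {
            done[[length(done) + 1L]] <- finalize_track(tr, dt, tr$misses)
          } else keep[i] <- TRUE
        }
      }
      active <- active[keep]
      for (j in assoc$unassigned) {
        active[[length(active) + 1L]] <- new_track(next_k, f, det[j, ], zid[j], params)
        next_k <- next_k + 1L
      }
    } else {
      for (j in seq_along(zid)) {
        active[[length(active) + 1L]] <- new_track(next_k, f, zs[j, ], zid[j], params)
        next_k <- next_k + 1L
      }
    }
  }
  for (tr in active) done[[length(done) + 1L]] <- finalize_track(tr, dt)
  done <- Filter(Negate(is.null), done)
  done <- done[order(vapply(done, `[[`, numeric(1), "t_start"),
                     vapply(done, `[[`, integer(1), "k"))]
  structure(list(tracklets = done, params = params), class = "tracklet_set")
}

#' @export
print.tracklet_set <- function(x, ...) {
  ns <- vapply(x$tracklets, function(tr) nrow(tr$states), integer(1))
  cat(sprintf("<tracklet_set> %d tracklets, %d states total\n",
              length(x$tracklets), sum(ns)))
  invisible(x)
}

#' @export
as.data.frame.tracklet_set <- function(x, ...) {
  do.call(rbind, lapply(x$tracklets, function(tr)
    cbind(k = tr$k, tr$states)))
}

#' Write / read a tracklet table
#'
#' Columns \code{k, t, p_x, p_y, v_x, v_y, confirmed, detection_id} plus
#' derived kinematics when present.
#'
#' @param tracklets a \code{tracklet_set} or its data frame form.
#' @param path CSV path.
#' @export
write_tracklets <- function(tracklets, path) {
  df <- if (inherits(tracklets, "tracklet_set")) as.data.frame(tracklets) else tracklets
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_sig)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracklets
#' @export
read_tracklets <- function(path) read.csv(path, stringsAsFactors = FALSE)
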