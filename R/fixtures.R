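# Named scenario bundles used by the test suite, documentation and the
# command-line `simulate` stage.

straight_line_detections <- function(camera, x0, y0, vx, frames, drop_frames = integer(0),
                                     box_size = c(2.2, 1.0)) {
  # exact (noise-free, surface-swimming) detections for one camera
  keep <- setdiff(frames, drop_frames)
  t <- keep * 0.1
  cx <- x0 + vx * t; cy <- rep(y0, length(t))
  hx <- box_size[1] / 2; hy <- box_size[2] / 2
  q <- cbind(project_points(camera$H_inv, cbind(cx - hx, cy - hy)),
             project_points(camera$H_inv, cbind(cx + hx, cy - hy)),
             project_points(camera$H_inv, cbind(cx + hx, cy + hy)),
             project_points(camera$H_inv, cbind(cx - hx, cy + hy)))
  data.frame(t_s = t, camera_id = camera$camera_id,
             x1 = q[, 1], y1 = q[, 2], x2 = q[, 3], y2 = q[, 4],
             x3 = q[, 5], y3 = q[, 6], x4 = q[, 7], y4 = q[, 8],
             confidence = 0.99, detection_id = seq_along(t))
}

#' Compressed pseudo-day block schedule
#'
#' A 30-minute analogue of the daily observation schedule: five OTS blocks
#' of 240 s interleaved with four ITS blocks of 150 s, anchored at a
#' nominal 08:00 session start. Used by the \code{perimeter_day} fixture
#' so block statistics can be exercised end-to-end at desk scale.
#'
#' @param session_start_s clock time of scenario t = 0 (s since midnight),
#'   default 08:00.
#' @return A \code{\link{block_schedule}}.
#' @export
pseudo_day_schedule <- function(session_start_s = 8 * 3600) {
  labs <- c("OTS1", "ITS1", "OTS2", "ITS2", "OTS3", "ITS3", "OTS4", "ITS4", "OTS5")
  durs <- c(240, 150, 240, 150, 240, 150, 240, 150, 240)
  ends <- cumsum(durs)
  block_schedule(data.frame(
    label = labs, type = substr(labs, 1, 3),
    start = session_start_s + c(0, head(ends, -1)),
    end = session_start_s + ends, stringsAsFactors = FALSE))
}

pseudo_day_modes <- function() {
  # per-block behaviour mixes; swimming speeds follow the typical observed
  # block means (1.30-1.57 m/s)
  sch <- pseudo_day_schedule(0)   # relative seconds
  mode <- c("perimeter", "stationing", "mixed", "mixed", "perimeter",
            "stationing", "perimeter", "mixed", "perimeter")
  speed <- c(1.30, 0.3, 1.57, 1.45, 1.45, 0.3, 1.41, 1.39, 1.43)
  data.frame(start_s = sch$start_s, end_s = sch$end_s, mode = mode, speed = speed)
}

#' Build a named synthetic scenario bundle
#'
#' Self-contained scenario bundles consumed by the tests and docs:
#' \describe{
#'   \item{two_animal_crossing}{two noise-free animals on parallel
#'     opposite-heading paths 3 m apart (identity-conservation cases).}
#'   \item{gap_bridge}{a single straight constant-velocity path with
#'     exactly one 4-frame detection gap.}
#'   \item{deactivation}{detections that cease permanently at frame 50 of
#'     a 70-frame recording.}
#'   \item{stationing_session}{all animals stationing for 5 minutes.}
#'   \item{perimeter_day}{7 animals, 30 min, noise 0.1 m, dropout 0.2,
#'     with the compressed 5 OTS + 4 ITS pseudo-day schedule and distinct
#'     per-block behaviour mixes.}
#' }
#'
#' @param name fixture name (see above).
#' @param dir optional directory; when given, the bundle is written as
#'   \code{config.json}, \code{detections.csv}, \code{truth.csv} (and
#'   \code{tracks.csv}, \code{schedule.csv} where applicable).
#' @param seed RNG seed, default 1.
#' @return List with (depending on the fixture) \code{detections},
#'   \code{truth}, \code{tracks}, \code{cameras}, \code{schedule},
#'   \code{config}, \code{session_start_s}.
#' @export
make_fixture <- function(name, dir = NULL, seed = 1L) {
  cams <- make_default_cameras()
  bundle <- switch(
    name,
    gap_bridge = {
      det <- straight_line_detections(cams$left, x0 = 2, y0 = 6, vx = 1, frames = 0:99,
                                      drop_frames = 50:53)
      list(detections = det, truth = NULL, cameras = cams,
           config = list(name = name, gap_frames = 4, t_end = 9.9))
    },
    deactivation = {
      det <- straight_line_detections(cams$left, x0 = 2, y0 = 6, vx = 1, frames = 0:49)
      list(detections = det, truth = NULL, cameras = cams,
           config = list(name = name, last_detection_frame = 49, t_end = 6.9))
    },
    two_animal_crossing = {
      d1 <- straight_line_detections(cams$left, x0 = 1, y0 = 4.5, vx = 1.4, frames = 0:80)
      d2 <- straight_line_detections(cams$left, x0 = 13, y0 = 7.5, vx = -1.4, frames = 0:80)
      d2$detection_id <- d2$detection_id + nrow(d1)
      truth <- data.frame(detection_id = c(d1$detection_id, d2$detection_id),
                          animal = rep(1:2, c(nrow(d1), nrow(d2))), is_drain = FALSE)
      list(detections = rbind(d1, d2), truth = truth, cameras = cams,
           config = list(name = name, t_end = 8))
    },
    stationing_session = {
      cfg <- scenario_config(n_animals = 7, duration = 300,
                             mode_schedule = data.frame(start_s = 0, end_s = 300,
                                                        mode = "stationing", speed = 0.3),
                             seed = seed)
      tracks <- simulate_tracks(cfg)
      sens <- sensor_model(cams)
      rd <- render_detections(tracks, sens, seed = seed + 1L)
      list(detections = rd$detections, truth = rd$truth, tracks = tracks,
           cameras = cams, config = cfg, session_start_s = 8 * 3600)
    },
    perimeter_day = {
      cfg <- scenario_config(n_animals = 7, duration = 1800,
                             mode_schedule = pseudo_day_modes(), seed = seed)
      tracks <- simulate_tracks(cfg)
      sens <- sensor_model(cams)
      rd <- render_detections(tracks, sens, seed = seed + 1L)
      list(detections = rd$detections, truth = rd$truth, tracks = tracks,
           cameras = cams, config = cfg, schedule = pseudo_day_schedule(),
           session_start_s = 8 * 3600)
    },
    stop("make_fixture: unknown fixture '", name, "'")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(bundle$detections, file.path(dir, "detections.csv"), row.names = FALSE)
    if (!is.null(bundle$truth))
      write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
    if (!is.null(bundle$tracks))
      write.csv(bundle$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
    if (!is.null(bundle$schedule))
      write.csv(as.data.frame(bundle$schedule)[, c("label", "type", "start_s", "end_s")],
                file.path(dir, "schedule.csv"), row.names = FALSE)
    write_camera_json(bundle$cameras$left, file.path(dir, "camera_left.json"))
    write_camera_json(bundle$cameras$right, file.path(dir, "camera_right.json"))
    cfg <- bundle$config
    if (inherits(cfg, "scenario_config"))
      cfg <- list(name = name, n_animals = cfg$n_animals, duration = cfg$duration,
                  rate_hz = cfg$rate_hz, seed = cfg$seed,
                  mode_schedule = cfg$mode_schedule)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    return(invisible(bundle))
  }
  bundle
}
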