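# Stage orchestration: mesh -> track -> map -> stats, with serialized
# intermediate artifacts so each stage is independently re-runnable.

#' Load a pipeline configuration
#'
#' YAML or JSON. Paths are resolved relative to the config file. Stage
#' parameters default to the standard values (0.95 confidence, 0.8 m gate,
#' 5 misses, 0.2 m detection error, 7 m max depth, s = 20 px/m, 10 Hz,
#' 1e5/1e4 subsample sizes, alpha_crit 0.001, 0.5 m/s static threshold).
#'
#' @param path config file path.
#' @return List of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(confidence_threshold = 0.95, gate_radius = 0.8, max_misses = 5,
                   process_noise = 0.5, measurement_noise = 0.04,
                   sigma_m = 0.2, max_depth = 7, map_scale = 20, rate_hz = 10,
                   entropy_subsample = 1e5, ks_subsample = 1e4,
                   alpha_crit = 0.001, sd_window = 21,
                   session_start = "08:00", seed = 1)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  base <- dirname(normalizePath(path))
  for (nm in grep("_path$", names(cfg), value = TRUE)) {
    if (!file.exists(cfg[[nm]])) cfg[[nm]] <- file.path(base, cfg[[nm]])
    if (!file.exists(cfg[[nm]]))
      stop("read_pipeline_config: missing input file for ", nm, ": ", cfg[[nm]])
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

load_habitat_polygon <- function(path) {
  p <- read.csv(path)
  as.matrix(p[, c("x_m", "y_m")])
}

stage_artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, producer) {
  p <- stage_artifact(out_dir, name)
  if (!file.exists(p))
    stop("pipeline: missing artifact '", name, "'; run the '", producer,
         "' stage first")
  p
}

#' Run the tracking pipeline
#'
#' Executes the requested stages in order (\code{mesh}, \code{track},
#' \code{map}, \code{stats}); each stage reads its predecessor's
#' serialized output from \code{out_dir} so any stage can be re-run in
#' isolation. A run manifest (parameters, seed, input digests, counts) is
#' written alongside the outputs.
#'
#' @param config a \code{\link{read_pipeline_config}} result, or a list
#'   with the same fields (must include \code{detections_path},
#'   \code{calibration} inputs — either \code{camera_left_path} /
#'   \code{camera_right_path} JSON models or a \code{calibration_path}
#'   correspondence table plus camera placement fields — and
#'   \code{habitat_path}; \code{schedule_path} is optional and defaults to
#'   the standard daily schedule).
#' @param out_dir output directory.
#' @param stages subset of \code{c("mesh", "track", "map", "stats")}.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("mesh", "track", "map", "stats")) {
  stages <- match.arg(stages, c("mesh", "track", "map", "stats"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  habitat <- load_habitat_polygon(config$habitat_path)

  cameras <- if (!is.null(config$camera_left_path)) {
    list(left = read_camera_json(config$camera_left_path),
         right = read_camera_json(config$camera_right_path))
  } else {
    cal <- read_calibration(config$calibration_path)
    mk <- function(cid, pos, h) {
      g <- cal[cal$camera_id == cid, ]
      camera_model(cid, as.matrix(g[, c("u_px", "v_px")]), as.matrix(g[, c("x_m", "y_m")]),
                   image_size = unlist(config$image_size),
                   world_position = pos, height_above_water = h)
    }
    list(left = mk("left", unlist(config$camera_left_position), config$camera_height),
         right = mk("right", unlist(config$camera_right_position), config$camera_height))
  }
  overlap <- compute_overlap(cameras$left, cameras$right)
  manifest <- list(seed = seed, stages = stages,
                   parameters = config[setdiff(names(config), "class")],
                   l_s = overlap$l_s)

  if ("mesh" %in% stages) {
    det <- read_detections(config$detections_path)
    message(sprintf("[mesh] %d raw detections, frames %.1f-%.1f s",
                    nrow(det), min(det$t), max(det$t)))
    meshed <- mesh_detections(det, cameras$left, cameras$right, overlap, habitat,
                              confidence_threshold = config$confidence_threshold)
    write_meshed(meshed, stage_artifact(out_dir, "meshed.csv"))
    manifest$mesh <- list(n_raw = nrow(det), n_meshed = nrow(meshed),
                          n_clamped = attr(meshed, "n_clamped"))
    message(sprintf("[mesh] %d meshed detections", nrow(meshed)))
  }

  if ("track" %in% stages) {
    meshed <- read.csv(require_artifact(out_dir, "meshed.csv", "mesh"))
    params <- tracker_params(dt = 1 / config$rate_hz, q = config$process_noise,
                             r = config$measurement_noise,
                             gate_radius = config$gate_radius,
                             max_misses = config$max_misses)
    ts <- track_detections(meshed, params, t_end = max(meshed$t))
    kin <- tracklet_kinematics(ts)
    df <- as.data.frame(ts)
    ki <- match(paste(df$k, round(df$t, 3)), paste(kin$k, round(kin$t, 3)))
    df$speed <- kin$speed[ki]; df$yaw <- kin$yaw[ki]
    df$yaw_rate <- kin$yaw_rate[ki]; df$movement_state <- kin$movement_state[ki]
    write_tracklets(df, stage_artifact(out_dir, "tracklets.csv"))
    manifest$track <- list(n_tracklets = length(ts$tracklets),
                           n_states = nrow(df),
                           n_confirmed = sum(df$confirmed))
    message(sprintf("[track] %d tracklets, %d states", length(ts$tracklets), nrow(df)))
  }

  if ("map" %in% stages) {
    meshed <- read.csv(require_artifact(out_dir, "meshed.csv", "mesh"))
    tk <- read.csv(require_artifact(out_dir, "tracklets.csv", "track"))
    conf <- tk[tk$confirmed & !is.na(tk$speed), , drop = FALSE]
    idx <- match(meshed$detection_id, conf$detection_id)
    meshed$speed <- conf$speed[idx]; meshed$yaw <- conf$yaw[idx]
    meshed$movement_state <- conf$movement_state[idx]
    maps <- accumulate_maps(meshed, cameras, habitat, depth_pdf(max_depth = config$max_depth),
                            s = config$map_scale, sigma_m = config$sigma_m)
    write_maps(maps, out_dir, "all")
    for (st in c("static", "dynamic")) {
      sub <- meshed[!is.na(meshed$movement_state) & meshed$movement_state == st, , drop = FALSE]
      if (nrow(sub))
        write_maps(accumulate_maps(sub, cameras, habitat,
                                   depth_pdf(max_depth = config$max_depth),
                                   s = config$map_scale, sigma_m = config$sigma_m),
                   out_dir, st)
    }
    manifest$map <- list(n_injected = maps$n_injected,
                         n_without_kinematics = maps$n_without_kinematics)
    message(sprintf("[map] injected %d detections", maps$n_injected))
  }

  if ("stats" %in% stages) {
    tk <- read.csv(require_artifact(out_dir, "tracklets.csv", "track"))
    kin <- tk[tk$confirmed & !is.na(tk$speed), , drop = FALSE]
    schedule <- if (!is.null(config$schedule_path)) {
      s <- read.csv(config$schedule_path)
      block_schedule(data.frame(label = s$label, type = s$type,
                                start = s$start_s, end = s$end_s))
    } else block_schedule()
    start_s <- if (is.character(config$session_start)) parse_clock(config$session_start)
               else config$session_start
    kin$clock_s <- start_s + kin$t
    kin <- assign_blocks(kin, schedule)
    ent <- block_entropy(kin, n_sub = config$entropy_subsample, seed = seed)
    ms <- block_metric_samples(kin, sd_window = config$sd_window)
    ks <- compare_blocks(ms, n_sub = config$ks_subsample, seed = seed,
                         alpha_crit = config$alpha_crit)
    summ <- block_summary(kin)
    fmt <- function(df) { num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], format_sig); df }
    write.csv(fmt(ks), stage_artifact(out_dir, "ks_table.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(entropy = fmt(ent), summary = fmt(summ)),
                         stage_artifact(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$stats <- list(n_blocks = nrow(ent),
                           n_comparisons = if (is.null(ks)) 0L else nrow(ks))
    message(sprintf("[stats] %d blocks, %d K-S comparisons", nrow(ent),
                    if (is.null(ks)) 0L else nrow(ks)))
  }

  jsonlite::write_json(manifest, stage_artifact(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Summarize pipeline artifacts as a human-readable report
#'
#' Per-block static/dynamic fractions, mean speed (m/s) and mean yaw rate
#' (deg/s), the per-block joint-entropy table, and the K-S comparison
#' table.
#'
#' @param out_dir pipeline output directory (stats stage complete).
#' @return The report, invisibly, as a character vector of lines (also
#'   printed).
#' @export
summarize_pipeline <- function(out_dir) {
  st <- jsonlite::read_json(require_artifact(out_dir, "stats.json", "stats"),
                            simplifyVector = TRUE)
  ks <- read.csv(require_artifact(out_dir, "ks_table.csv", "stats"))
  lines <- c("== Block summary ==",
             sprintf("%-6s %-4s %8s %12s %18s %12s %12s", "block", "type", "n",
                     "speed(m/s)", "yaw_rate(deg/s)", "static", "dynamic"))
  s <- st$summary
  for (i in seq_len(nrow(s)))
    lines <- c(lines, sprintf("%-6s %-4s %8d %12.3f %18.3f %12.3f %12.3f",
                              s$block[i], s$type[i], s$n[i], s$mean_speed[i],
                              s$mean_yaw_rate_deg_s[i], s$frac_static[i],
                              s$frac_dynamic[i]))
  lines <- c(lines, "", "== Joint differential entropy (speed, yaw) ==",
             sprintf("%-6s %-4s %10s", "block", "type", "h (nats)"))
  e <- st$entropy
  for (i in seq_len(nrow(e)))
    lines <- c(lines, sprintf("%-6s %-4s %10.3f", e$block[i], e$type[i], e$h[i]))
  lines <- c(lines, "", "== Kolmogorov-Smirnov comparisons ==",
             sprintf("%-12s %-6s %-6s %10s %10s %5s", "metric", "blk_i", "blk_j",
                     "delta_ks", "alpha", "sig"))
  for (i in seq_len(nrow(ks)))
    lines <- c(lines, sprintf("%-12s %-6s %-6s %10.3f %10.3g %5s", ks$metric[i],
                              ks$block_i[i], ks$block_j[i], ks$delta_ks[i],
                              ks$alpha[i], ifelse(ks$significant[i], "*", "")))
  cat(lines, sep = "\n")
  invisible(lines)
}
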