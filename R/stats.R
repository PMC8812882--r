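# Block-wise kinematic statistics: time-block partitioning, joint
# differential entropy of speed and yaw, and two-sample Kolmogorov-Smirnov
# comparisons.

parse_clock <- function(x) {
  # "HH:MM" or "HH:MM:SS" -> seconds since midnight
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(v) {
    v <- as.numeric(v)
    v[1] * 3600 + v[2] * 60 + if (length(v) > 2) v[3] else 0
  }, numeric(1))
}

#' Time-block schedule
#'
#' Observation blocks alternate between out-of-training-session (OTS) and
#' in-training-session (ITS) periods. The default is the facility's
#' regular daily schedule: five OTS blocks (08:00-09:30, 10:00-11:30,
#' 12:00-13:00, 13:30-14:30, 15:00-16:00) interleaved with four 30-minute
#' ITS blocks.
#'
#' @param blocks optional data frame with columns \code{label, type,
#'   start, end} (clock strings "HH:MM" or seconds since midnight).
#' @return Data frame of class \code{block_schedule} with numeric
#'   \code{start_s}, \code{end_s}.
#' @export
block_schedule <- function(blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- data.frame(
      label = c("OTS1", "ITS1", "OTS2", "ITS2", "OTS3", "ITS3", "OTS4", "ITS4", "OTS5"),
      type = c("OTS", "ITS", "OTS", "ITS", "OTS", "ITS", "OTS", "ITS", "OTS"),
      start = c("08:00", "09:30", "10:00", "11:30", "12:00", "13:00", "13:30", "14:30", "15:00"),
      end = c("09:30", "10:00", "11:30", "12:00", "13:00", "13:30", "14:30", "15:00", "16:00"),
      stringsAsFactors = FALSE)
  }
  blocks$start_s <- if (is.numeric(blocks$start)) blocks$start else parse_clock(blocks$start)
  blocks$end_s <- if (is.numeric(blocks$end)) blocks$end else parse_clock(blocks$end)
  stopifnot(all(blocks$end_s > blocks$start_s),
            all(blocks$type %in% c("OTS", "ITS")))
  o <- order(blocks$start_s)
  if (any(blocks$start_s[o][-1] < blocks$end_s[o][-nrow(blocks)]))
    stop("block_schedule: overlapping block intervals")
  class(blocks) <- c("block_schedule", "data.frame")
  blocks
}

#' Assign samples to schedule blocks
#'
#' Block intervals are half-open \[start, end): a sample exactly on a
#' boundary belongs to the later block. Samples outside every block are
#' dropped with a message.
#'
#' @param samples data frame with a \code{clock_s} column (seconds since
#'   midnight).
#' @param schedule a \code{\link{block_schedule}}.
#' @return \code{samples} with \code{block} and \code{block_type} columns,
#'   rows outside the schedule removed.
#' @export
assign_blocks <- function(samples, schedule = block_schedule()) {
  blk <- rep(NA_character_, nrow(samples))
  typ <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(schedule))) {
    sel <- samples$clock_s >= schedule$start_s[i] & samples$clock_s < schedule$end_s[i]
    blk[sel] <- schedule$label[i]
    typ[sel] <- schedule$type[i]
  }
  dropped <- sum(is.na(blk))
  if (dropped) message("assign_blocks: dropped ", dropped, " samples outside the schedule")
  samples$block <- blk
  samples$block_type <- typ
  samples[!is.na(blk), , drop = FALSE]
}

#' Deterministic seed fan-out
#'
#' Derives a reproducible sub-seed from a master seed and a string key
#' (e.g. block and metric labels) so that any single comparison can be
#' re-run in isolation.
#'
#' @param master_seed integer master seed.
#' @param ... labels combined into the key.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
fan_seed <- function(master_seed, ...) {
  key <- paste(..., sep = "/")
  h <- as.numeric(master_seed) %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Seeded uniform subsample
#'
#' Uniform random subsample of size n, reproducible under the seed. When n
#' exceeds the available samples, sampling is done with replacement (with
#' a message).
#'
#' @param values numeric vector (or indices).
#' @param n subsample size.
#' @param seed integer seed.
#' @return Length-n vector.
#' @export
subsample_values <- function(values, n, seed) {
  if (!length(values)) stop("subsample_values: empty input")
  replace <- n > length(values)
  if (replace) message("subsample_values: n exceeds available samples; sampling with replacement")
  withr::with_seed(seed, sample(values, n, replace = replace))
}

#' Joint speed/yaw histogram density
#'
#' 2D histogram density estimate of the joint speed/yaw distribution:
#' counts over a bins x bins grid divided by \code{n * ds * dpsi}.
#'
#' @param speed,yaw paired samples (m/s and rad).
#' @param bins bins per axis, default 64.
#' @param speed_range default \code{c(0, max(speed))}.
#' @param yaw_range default \code{c(-pi, pi)}.
#' @return Object of class \code{joint_pdf}: density matrix \code{f}
#'   (speed along rows), bin widths \code{ds}, \code{dpsi}, sample size
#'   \code{n}.
#' @export
estimate_joint_pdf <- function(speed, yaw, bins = 64L,
                               speed_range = c(0, max(speed)),
                               yaw_range = c(-pi, pi)) {
  stopifnot(length(speed) == length(yaw))
  if (diff(speed_range) <= 0 || diff(yaw_range) <= 0)
    stop("estimate_joint_pdf: degenerate sample range; add jitter or widen the range")
  ds <- diff(speed_range) / bins
  dpsi <- diff(yaw_range) / bins
  i <- pmin(pmax(ceiling((speed - speed_range[1]) / ds), 1L), bins)
  j <- pmin(pmax(ceiling((yaw - yaw_range[1]) / dpsi), 1L), bins)
  n <- length(speed)
  cnt <- matrix(tabulate((j - 1L) * bins + i, nbins = bins * bins), bins, bins)
  structure(list(f = cnt / (n * ds * dpsi), ds = ds, dpsi = dpsi, n = n,
                 bins = bins, speed_range = speed_range, yaw_range = yaw_range),
            class = "joint_pdf")
}

#' Joint differential entropy of a speed/yaw PDF
#'
#' Discretized differential entropy in nats,
#' \eqn{h = -\sum f \ln(f) \, \Delta s \, \Delta\psi} over non-empty
#' cells. By default the Miller-Madow bias correction
#' \eqn{(m_{occ} - 1) / (2n)} is added, which removes most of the
#' finite-sample downward bias of the plug-in estimator.
#'
#' @param pdf a \code{\link{estimate_joint_pdf}} result.
#' @param correction apply the Miller-Madow correction, default TRUE.
#' @return Object of class \code{entropy_result}: \code{h} (nats),
#'   \code{n}, \code{bins}, \code{correction}.
#' @export
joint_differential_entropy <- function(pdf, correction = TRUE) {
  f <- pdf$f
  nz <- f > 0
  h <- -sum(f[nz] * log(f[nz])) * pdf$ds * pdf$dpsi
  if (correction) h <- h + (sum(nz) - 1) / (2 * pdf$n)
  structure(list(h = h, n = pdf$n, bins = pdf$bins, correction = correction),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("joint differential entropy h = %.4f nats (n = %d, %d^2 bins%s)\n",
              x$h, x$n, x$bins, if (x$correction) ", bias-corrected" else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The K-S distance is the exact supremum of the absolute difference of
#' the two empirical CDFs over the pooled sample; the significance level
#' is the asymptotic Kolmogorov distribution evaluated at
#' \eqn{\sqrt{n_e} \Delta_{ks}} with effective size
#' \eqn{n_e = n_a n_b / (n_a + n_b)}.
#'
#' @param a,b numeric samples (length >= 2 each).
#' @return Object of class \code{ks_result}: \code{delta_ks},
#'   \code{alpha}, \code{n_eff}.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  z <- sort(unique(c(a, b)))
  d <- max(abs(ecdf(a)(z) - ecdf(b)(z)))
  ne <- length(a) * length(b) / (length(a) + length(b))
  x <- sqrt(ne) * d
  k <- 1:101
  alpha <- if (x < 1e-8) 1 else min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))))
  structure(list(delta_ks = d, alpha = alpha, n_eff = ne), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample K-S: delta_ks = %.4f, alpha = %.4g (n_eff = %.1f)\n",
              x$delta_ks, x$alpha, x$n_eff))
  invisible(x)
}

#' Collect per-block metric samples
#'
#' Builds the six comparison metrics — speed, yaw, yaw rate and their
#' rolling standard deviations — as a long data frame of per-step samples
#' with block labels.
#'
#' @param kinematics block-assigned kinematics (with \code{block},
#'   \code{block_type} columns).
#' @param sd_window rolling window for the std-dev metrics (steps),
#'   default 21.
#' @return Data frame \code{block, block_type, metric, value}.
#' @export
block_metric_samples <- function(kinematics, sd_window = 21L) {
  base <- rbind(
    data.frame(block = kinematics$block, block_type = kinematics$block_type,
               metric = "speed", value = kinematics$speed),
    data.frame(block = kinematics$block, block_type = kinematics$block_type,
               metric = "yaw", value = kinematics$yaw),
    data.frame(block = kinematics$block, block_type = kinematics$block_type,
               metric = "yaw_rate", value = kinematics$yaw_rate))
  sds <- rolling_std_metrics(kinematics, window = sd_window)
  if (nrow(sds)) {
    ix <- match(paste(sds$k, sds$t), paste(kinematics$k, kinematics$t))
    sdl <- rbind(
      data.frame(block = kinematics$block[ix], block_type = kinematics$block_type[ix],
                 metric = "speed_sd", value = sds$speed_sd),
      data.frame(block = kinematics$block[ix], block_type = kinematics$block_type[ix],
                 metric = "yaw_sd", value = sds$yaw_sd),
      data.frame(block = kinematics$block[ix], block_type = kinematics$block_type[ix],
                 metric = "yaw_rate_sd", value = sds$yaw_rate_sd))
    base <- rbind(base, sdl)
  }
  base[!is.na(base$block) & !is.na(base$value), , drop = FALSE]
}

#' Per-block joint entropy of speed and yaw
#'
#' For each block, speed/yaw pairs are subsampled (default 1e5 samples,
#' seeded per block from the master seed), binned into the joint PDF and
#' reduced to the joint differential entropy.
#'
#' @param kinematics block-assigned kinematics.
#' @param n_sub subsample size, default 1e5.
#' @param seed master seed.
#' @param bins histogram bins per axis, default 64.
#' @return Data frame \code{block, type, h, n}.
#' @export
block_entropy <- function(kinematics, n_sub = 1e5, seed = 1L, bins = 64L) {
  out <- NULL
  for (b in unique(kinematics$block)) {
    g <- kinematics[kinematics$block == b, , drop = FALSE]
    idx <- subsample_values(seq_len(nrow(g)), n_sub, fan_seed(seed, "entropy", b))
    pdf <- estimate_joint_pdf(g$speed[idx], g$yaw[idx], bins = bins)
    h <- joint_differential_entropy(pdf)
    out <- rbind(out, data.frame(block = b, type = g$block_type[1], h = h$h,
                                 n = h$n))
  }
  out[order(out$type, out$block), , drop = FALSE]
}

#' Pairwise K-S comparison of blocks
#'
#' All pairs of blocks of the same type (OTS with OTS, ITS with ITS) are
#' compared for each metric on fresh seeded subsamples (default 1e4 per
#' side). Cross-type comparisons are refused. Significance is judged
#' against \code{alpha_crit} (default 0.001, appropriate for the large
#' subsample sizes).
#'
#' @param metric_samples output of \code{\link{block_metric_samples}}.
#' @param n_sub subsample size per side, default 1e4.
#' @param seed master seed.
#' @param alpha_crit significance threshold, default 0.001.
#' @param pairs optional data frame \code{block_i, block_j} restricting
#'   the comparisons; a cross-type pair raises an error.
#' @return Data frame \code{metric, type, block_i, block_j, delta_ks,
#'   alpha, significant}.
#' @export
compare_blocks <- function(metric_samples, n_sub = 1e4, seed = 1L,
                           alpha_crit = 0.001, pairs = NULL) {
  blocks <- unique(metric_samples[, c("block", "block_type")])
  btype <- setNames(blocks$block_type, blocks$block)
  if (is.null(pairs)) {
    pairs <- NULL
    for (ty in unique(blocks$block_type)) {
      bs <- sort(blocks$block[blocks$block_type == ty])
      if (length(bs) < 2) next
      cmb <- t(utils::combn(bs, 2))
      pairs <- rbind(pairs, data.frame(block_i = cmb[, 1], block_j = cmb[, 2]))
    }
    if (is.null(pairs)) stop("compare_blocks: need at least two blocks of one type")
  }
  for (r in seq_len(nrow(pairs)))
    if (btype[[pairs$block_i[r]]] != btype[[pairs$block_j[r]]])
      stop("compare_blocks: cross-type comparison refused (", pairs$block_i[r],
           " vs ", pairs$block_j[r], ")")
  out <- NULL
  for (met in unique(metric_samples$metric)) {
    ms <- metric_samples[metric_samples$metric == met, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      bi <- pairs$block_i[r]; bj <- pairs$block_j[r]
      vi <- ms$value[ms$block == bi]; vj <- ms$value[ms$block == bj]
      if (length(vi) < 2 || length(vj) < 2) next
      si <- subsample_values(vi, n_sub, fan_seed(seed, "ks", bi, met))
      sj <- subsample_values(vj, n_sub, fan_seed(seed, "ks", bj, met))
      ks <- ks_two_sample(si, sj)
      out <- rbind(out, data.frame(metric = met, type = btype[[bi]],
                                   block_i = bi, block_j = bj,
                                   delta_ks = ks$delta_ks, alpha = ks$alpha,
                                   significant = ks$alpha < alpha_crit))
    }
  }
  out
}

#' Per-block summary in reporting units
#'
#' Mean speed (m/s), mean yaw rate (converted to deg/s for readability)
#' and static/dynamic fractions per block.
#'
#' @param kinematics block-assigned kinematics.
#' @return Data frame \code{block, type, n, mean_speed, mean_yaw_rate_deg_s,
#'   frac_static, frac_dynamic}.
#' @export
block_summary <- function(kinematics) {
  out <- NULL
  for (b in unique(kinematics$block)) {
    g <- kinematics[kinematics$block == b, , drop = FALSE]
    fs <- mean(g$movement_state == "static")
    out <- rbind(out, data.frame(
      block = b, type = g$block_type[1], n = nrow(g),
      mean_speed = mean(g$speed),
      mean_yaw_rate_deg_s = mean(g$yaw_rate) * 180 / pi,
      frac_static = fs, frac_dynamic = 1 - fs))
  }
  out[order(out$type, out$block), , drop = FALSE]
}
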