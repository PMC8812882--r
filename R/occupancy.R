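# Uncertainty-aware habitat maps. Each detection is injected as a 2D
# probability kernel whose minor axis is the camera detection noise and
# whose major axis spreads along the direction of the depth-induced
# position error.
#
# Map grids are matrices with x along columns and y along rows; pixel
# (i, j) covers world x in [(j-1)/s, j/s) and y in [(i-1)/s, i/s) at map
# scale s px/m (default 20, i.e. 1 px = 5 cm).

#' Discretized animal-depth probability density
#'
#' A stand-in for tag-measured depth-occupancy data: a truncated
#' exponential over \[0, max_depth\] (animals spend most time near the
#' surface), normalized to sum 1 after discretization.
#'
#' @param max_depth maximum habitat depth (m), default 7.
#' @param mean_depth nominal mean of the (untruncated) exponential (m),
#'   default 1.5.
#' @param n number of support samples, default 128.
#' @return Object of class \code{depth_pdf} with fields \code{depth} and
#'   \code{density}.
#' @export
depth_pdf <- function(max_depth = 7, mean_depth = 1.5, n = 128L) {
  stopifnot(max_depth > 0, mean_depth > 0)
  depth <- seq(0, max_depth, length.out = n)
  dens <- exp(-depth / mean_depth)
  structure(list(depth = depth, density = dens / sum(dens),
                 max_depth = max_depth, mean_depth = mean_depth),
            class = "depth_pdf")
}

#' Minor-axis Gaussian kernel
#'
#' 1D discrete Gaussian PDF representing the general camera detection
#' error, with \eqn{\sigma_{gauss} = \sigma_m s} pixels, support of
#' +/- 4 sigma, odd length, normalized to sum 1.
#'
#' @param sigma_m detection error (m), default 0.2.
#' @param s map scale (px/m), default 20.
#' @return Numeric vector (the kernel).
#' @export
minor_axis_kernel <- function(sigma_m = 0.2, s = 20) {
  stopifnot(sigma_m > 0, s > 0)
  sig <- sigma_m * s
  h <- ceiling(4 * sig)
  k <- dnorm(-h:h, 0, sig)
  k / sum(k)
}

#' Depth-driven error geometry of a detection
#'
#' Under a pinhole model, an animal at depth d whose surface image appears
#' at horizontal distance r from the camera's nadir is actually displaced
#' by \eqn{d \cdot r / h_c} further from the nadir (similar triangles with
#' camera height \eqn{h_c}). The maximum position error magnitude
#' \eqn{e_m} (in px at scale s) is this displacement at maximum depth; its
#' direction \eqn{\psi_m} points from the nadir toward the detection. An
#' optional flat-refraction factor (water index 1.33) scales the
#' displacement; it is off by default.
#'
#' @param u length-2 world detection position (m).
#' @param camera the observing \code{camera_model} (for meshed two-camera
#'   detections, the near camera per the mesh weights).
#' @param max_depth maximum animal depth (m), default 7.
#' @param s map scale (px/m), default 20.
#' @param snell apply the 1.33 refraction factor, default FALSE.
#' @return Object of class \code{error_geometry}: \code{e_m} (px),
#'   \code{psi_m} (rad), \code{s}, \code{truncated}.
#' @export
depth_error_geometry <- function(u, camera, max_depth = 7, s = 20, snell = FALSE) {
  h_c <- camera$height_above_water
  if (h_c <= 0) stop("depth_error_geometry: camera height must be positive")
  d <- u - camera$world_position
  r <- sqrt(sum(d^2))
  fac <- if (snell) 1.33 else 1
  e_m <- s * max_depth * r / h_c * fac
  psi_m <- if (r > 0) atan2(d[2], d[1]) else 0
  structure(list(e_m = e_m, psi_m = psi_m, s = s, truncated = FALSE),
            class = "error_geometry")
}

#' Truncate the error magnitude at the habitat perimeter
#'
#' The habitat wall is a hard constraint on animal positions: if the point
#' with maximum shift \eqn{p + e_m(\cos\psi_m, \sin\psi_m)} falls outside
#' the perimeter, \eqn{e_m} is reduced to the largest value keeping it
#' inside. The direction is unchanged.
#'
#' @param geom an \code{\link{depth_error_geometry}} result.
#' @param habitat_polygon perimeter polygon (m).
#' @param p length-2 detection position (m), inside the polygon.
#' @return Possibly-truncated \code{error_geometry}.
#' @export
truncate_error <- function(geom, habitat_polygon, p) {
  if (geom$e_m <= 0) return(geom)
  dir <- c(cos(geom$psi_m), sin(geom$psi_m))
  len_m <- geom$e_m / geom$s
  tip <- p + len_m * dir
  if (in_polygon(habitat_polygon, tip)) return(geom)
  t_exit <- ray_exit_distance(habitat_polygon, p, dir)
  if (is.finite(t_exit) && t_exit < len_m) {
    geom$e_m <- max(0, t_exit * geom$s * (1 - 1e-9))
    geom$truncated <- TRUE
  }
  geom
}

#' Major-axis PDF from the depth distribution
#'
#' The depth PDF is linearly resampled to \code{e_m} pixels — mapping the
#' 0..max-depth error range onto the 0..e_m pixel error range — and
#' convolved (full convolution) with the minor-axis kernel to fold in the
#' camera measurement noise. For \code{e_m < 1} px the depth contribution
#' vanishes and the minor kernel itself is returned.
#'
#' @param depth a \code{\link{depth_pdf}}.
#' @param D1 minor-axis kernel (from \code{\link{minor_axis_kernel}}).
#' @param e_m error extent in px.
#' @return Normalized numeric vector D2.
#' @export
major_axis_pdf <- function(depth, D1, e_m) {
  L <- round(e_m)
  if (L < 1) return(D1)
  dp <- if (L == 1) 1 else {
    g <- seq(0, 1, length.out = length(depth$density))
    approx(g, depth$density, seq(0, 1, length.out = L))$y
  }
  dp <- dp / sum(dp)
  D2 <- convolve(dp, rev(D1), type = "open")
  D2 / sum(D2)
}

rotate_kernel <- function(E, psi_m) {
  deg <- psi_m * 180 / pi
  # EBImage::rotate() turns the column axis to angle -a in our
  # (x = columns, y = rows) frame, so negate to rotate the major axis to +psi.
  F_ <- EBImage::rotate(E, -deg, filter = "bilinear", bg.col = 0)
  F_ <- pmax(as.matrix(F_), 0)
  F_ / sum(F_)
}

#' Build the rotated 2D occupancy kernel
#'
#' The unrotated kernel is the outer product \eqn{E = D_1^T D_2} (minor
#' axis along rows, major axis along columns), with the minor axis
#' zero-padded and centered to the major axis length. E is rotated by
#' \eqn{\psi_m} with a bilinear interpolating rotation on an expanded
#' canvas, clipped at zero and renormalized to sum 1.
#'
#' @param D1 minor-axis kernel.
#' @param D2 major-axis PDF.
#' @param psi_m rotation angle (rad).
#' @return Object of class \code{occupancy_kernel} with fields \code{F}
#'   (the rotated kernel matrix), \code{E}, \code{D1}, \code{D2},
#'   \code{psi_m}.
#' @export
build_kernel <- function(D1, D2, psi_m) {
  L <- max(length(D1), length(D2))
  pad_center <- function(v, L) {
    extra <- L - length(v)
    lo <- floor(extra / 2)
    c(rep(0, lo), v, rep(0, extra - lo))
  }
  E <- outer(pad_center(D1, L), pad_center(D2, L))
  F_ <- if (abs(psi_m) %% (2 * pi) < 1e-12) E else rotate_kernel(E, psi_m)
  structure(list(F = F_, E = E, D1 = D1, D2 = D2, psi_m = psi_m),
            class = "occupancy_kernel")
}

#' Blank habitat map set
#'
#' Allocates occupancy (M), speed-weighted (N) and velocity-component
#' (Qx, Qy) maps covering the habitat polygon's bounding box, rounded up
#' to whole metres so maps can later be subsampled to 1 px = 1 m.
#'
#' @param habitat_polygon perimeter polygon (m).
#' @param s map scale (px/m), default 20 (1 px = 5 cm).
#' @return Object of class \code{habitat_maps}.
#' @export
habitat_maps <- function(habitat_polygon, s = 20) {
  stopifnot(s > 0, s == round(s))
  nx <- ceiling(max(habitat_polygon[, 1])) * s
  ny <- ceiling(max(habitat_polygon[, 2])) * s
  z <- matrix(0, ny, nx)
  structure(list(M = z, N = z, Qx = z, Qy = z, s = s,
                 polygon = habitat_polygon,
                 n_injected = 0L, n_without_kinematics = 0L),
            class = "habitat_maps")
}

#' @export
print.habitat_maps <- function(x, ...) {
  cat(sprintf("<habitat_maps> %d x %d px at %d px/m; %d detections injected (%d without kinematics)\n",
              nrow(x$M), ncol(x$M), x$s, x$n_injected, x$n_without_kinematics))
  invisible(x)
}

#' Inject a kernel into a map
#'
#' Adds \code{F * value} into the map, centred at the half-error offset
#' point \eqn{[p_x + 0.5 e_m \cos\psi_m, p_y + 0.5 e_m \sin\psi_m]}. Kernel
#' mass that would fall off the map is redistributed by renormalizing the
#' clipped kernel, so each injection deposits exactly \code{value}.
#'
#' @param map map matrix (rows y, cols x).
#' @param F_ kernel matrix.
#' @param p length-2 detection position (m).
#' @param geom the detection's \code{error_geometry}.
#' @param s map scale (px/m).
#' @param value scalar weight, default 1.
#' @return The updated map matrix.
#' @export
inject <- function(map, F_, p, geom, s, value = 1) {
  cx <- p[1] + 0.5 * (geom$e_m / s) * cos(geom$psi_m)
  cy <- p[2] + 0.5 * (geom$e_m / s) * sin(geom$psi_m)
  kr <- (nrow(F_) + 1) / 2; kc <- (ncol(F_) + 1) / 2
  r0 <- round(cy * s + 0.5 - kr); c0 <- round(cx * s + 0.5 - kc)
  rows <- (r0 + 1):(r0 + nrow(F_)); cols <- (c0 + 1):(c0 + ncol(F_))
  rok <- rows >= 1 & rows <= nrow(map)
  cok <- cols >= 1 & cols <= ncol(map)
  Fc <- F_[rok, cok, drop = FALSE]
  m <- sum(Fc)
  if (m <= 0) return(map)
  map[rows[rok], cols[cok]] <- map[rows[rok], cols[cok]] + Fc * (value / m)
  map
}

#' Accumulate detections into habitat maps
#'
#' For each detection: the error geometry is computed from the near
#' camera, truncated at the habitat perimeter, turned into the rotated
#' occupancy kernel, and injected into the occupancy map M. Detections
#' carrying a kinematic sample additionally contribute \code{F * v} to the
#' speed-weighted map N and \code{F * v * cos(yaw)}, \code{F * v *
#' sin(yaw)} to the direction maps Qx, Qy; detections without kinematics
#' count for M only. Kernels are cached on (rounded e_m, 1-degree psi_m)
#' keys.
#'
#' @param detections data frame with \code{u_x, u_y, near_camera} and
#'   optionally \code{speed, yaw} (NA when no kinematic sample exists), as
#'   produced by \code{\link{link_detections}}.
#' @param cameras named list with \code{left} and \code{right} camera
#'   models.
#' @param habitat_polygon perimeter polygon (m).
#' @param depth a \code{\link{depth_pdf}}.
#' @param s map scale (px/m), default 20.
#' @param sigma_m minor-axis detection error (m), default 0.2.
#' @param max_depth maximum depth (m), default taken from \code{depth}.
#' @param snell refraction factor flag, default FALSE.
#' @return A \code{\link{habitat_maps}} object.
#' @export
accumulate_maps <- function(detections, cameras, habitat_polygon, depth = depth_pdf(),
                            s = 20, sigma_m = 0.2, max_depth = depth$max_depth,
                            snell = FALSE) {
  maps <- habitat_maps(habitat_polygon, s)
  D1 <- minor_axis_kernel(sigma_m, s)
  cache <- new.env(parent = emptyenv())
  has_kin <- if ("speed" %in% names(detections)) !is.na(detections$speed)
             else rep(FALSE, nrow(detections))
  for (i in seq_len(nrow(detections))) {
    p <- c(detections$u_x[i], detections$u_y[i])
    cam <- cameras[[detections$near_camera[i]]]
    geom <- depth_error_geometry(p, cam, max_depth = max_depth, s = s, snell = snell)
    geom <- truncate_error(geom, habitat_polygon, p)
    key <- sprintf("%d:%d", round(geom$e_m), round(geom$psi_m * 180 / pi))
    ker <- cache[[key]]
    if (is.null(ker)) {
      D2 <- major_axis_pdf(depth, D1, geom$e_m)
      ker <- build_kernel(D1, D2, geom$psi_m)
      cache[[key]] <- ker
    }
    maps$M <- inject(maps$M, ker$F, p, geom, s, 1)
    maps$n_injected <- maps$n_injected + 1L
    if (has_kin[i]) {
      v <- detections$speed[i]; th <- detections$yaw[i]
      maps$N <- inject(maps$N, ker$F, p, geom, s, v)
      maps$Qx <- inject(maps$Qx, ker$F, p, geom, s, v * cos(th))
      maps$Qy <- inject(maps$Qy, ker$F, p, geom, s, v * sin(th))
    } else {
      maps$n_without_kinematics <- maps$n_without_kinematics + 1L
    }
  }
  if (maps$n_without_kinematics)
    message("accumulate_maps: ", maps$n_without_kinematics,
            " detections without kinematics (occupancy only)")
  maps
}

#' Mean-speed map
#'
#' Element-wise N / M where the occupancy exceeds \code{eps}; other cells
#' are NA (undefined rather than zero, to avoid biasing averages).
#'
#' @param maps a \code{habitat_maps}.
#' @param eps occupancy floor, default 1e-12.
#' @return Matrix of mean speeds (m/s) with NA where undefined.
#' @export
speed_map <- function(maps, eps = 1e-12) {
  S <- maps$N / maps$M
  S[maps$M <= eps] <- NA_real_
  S
}

#' Subsample a map to a coarser scale
#'
#' Mass-conserving block sums for M, N, Qx, Qy. The mean-speed map is
#' subsampled as the ratio of the subsampled N and M (an occupancy-weighted
#' block mean).
#'
#' @param map map matrix at scale \code{s}.
#' @param s current scale (px/m).
#' @param target target scale (px/m), default 1.
#' @return Subsampled matrix.
#' @export
subsample_map <- function(map, s, target = 1) {
  f <- s / target
  if (f != round(f)) stop("subsample_map: scale ratio must be an integer")
  f <- as.integer(f)
  nr <- nrow(map) / f; nc <- ncol(map) / f
  if (nr != round(nr) || nc != round(nc))
    stop("subsample_map: map dimensions are not divisible by the block size")
  # fold columns then rows
  m1 <- map %*% kronecker(diag(nc), rep(1, f))
  t(t(m1) %*% kronecker(diag(nr), rep(1, f)))
}

#' Write habitat maps as TIFF rasters with a JSON sidecar
#'
#' Each map is written as a 32-bit float TIFF normalized by its maximum;
#' the sidecar records the normalization constants, scale and labels so
#' the rasters can be restored exactly.
#'
#' @param maps a \code{habitat_maps}.
#' @param dir output directory.
#' @param label block/state label used in filenames.
#' @return The sidecar path, invisibly.
#' @export
write_maps <- function(maps, dir, label = "all") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norms <- list()
  for (nm in c("M", "N", "Qx", "Qy")) {
    m <- maps[[nm]]
    mx <- max(abs(m))
    if (mx == 0) mx <- 1
    # shift/scale into [0,1] to satisfy the TIFF writer; sidecar restores
    tiff::writeTIFF((m / mx + 1) / 2, file.path(dir, sprintf("%s_%s.tif", label, nm)),
                    bits.per.sample = 32L)
    norms[[nm]] <- mx
  }
  sidecar <- file.path(dir, sprintf("%s_maps.json", label))
  jsonlite::write_json(list(label = label, scale_px_per_m = maps$s,
                            origin = c(0, 0), norms = norms,
                            n_injected = maps$n_injected,
                            n_without_kinematics = maps$n_without_kinematics,
                            polygon = maps$polygon),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read habitat maps written by \code{\link{write_maps}}
#'
#' @param dir directory containing the rasters.
#' @param label block/state label.
#' @return A \code{habitat_maps} object.
#' @export
read_maps <- function(dir, label = "all") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_maps.json", label)),
                              simplifyVector = TRUE)
  out <- list()
  for (nm in c("M", "N", "Qx", "Qy")) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", label, nm)))
    out[[nm]] <- (m * 2 - 1) * meta$norms[[nm]]
  }
  structure(c(out, list(s = meta$scale_px_per_m,
                        polygon = matrix(unlist(meta$polygon), ncol = 2),
                        n_injected = meta$n_injected,
                        n_without_kinematics = meta$n_without_kinematics)),
            class = "habitat_maps")
}

#' Plot a habitat map
#'
#' Basic raster display with the habitat perimeter overlaid.
#'
#' @param x a \code{habitat_maps}.
#' @param which one of "M", "N", "S", "Qx", "Qy".
#' @param ... passed to \code{graphics::image}.
#' @export
plot.habitat_maps <- function(x, which = "M", ...) {
  m <- if (which == "S") speed_map(x) else x[[which]]
  xs <- (seq_len(ncol(m)) - 0.5) / x$s
  ys <- (seq_len(nrow(m)) - 0.5) / x$s
  image(xs, ys, t(m), asp = 1, col = hcl.colors(64, "viridis"),
        xlab = "x (m)", ylab = "y (m)", main = which, ...)
  lines(rbind(x$polygon, x$polygon[1, ]), col = "white", lwd = 2)
  invisible(x)
}

#' Join meshed detections to tracklet kinematic samples
#'
#' Confirmed tracklet states carry the id of the detection they were
#' updated with; this merges each meshed detection with its tracklet's
#' speed and yaw at that step. Detections never associated with a tracklet
#' get NA kinematics (they still count for occupancy).
#'
#' @param meshed meshed detection data frame.
#' @param kinematics output of \code{\link{tracklet_kinematics}}.
#' @param confirmed_only use only detection-confirmed tracklet steps
#'   (default TRUE).
#' @return \code{meshed} with \code{k, speed, yaw, movement_state} columns
#'   appended.
#' @export
link_detections <- function(meshed, kinematics, confirmed_only = TRUE) {
  kk <- if (confirmed_only) kinematics[kinematics$confirmed, , drop = FALSE] else kinematics
  idx <- match(meshed$detection_id, kk$detection_id)
  meshed$k <- kk$k[idx]
  meshed$speed <- kk$speed[idx]
  meshed$yaw <- kk$yaw[idx]
  meshed$movement_state <- kk$movement_state[idx]
  meshed
}
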