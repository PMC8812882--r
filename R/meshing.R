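# Detection filtering, cross-camera conflict pairing, and centroid meshing.

#' Filter raw detections by detector confidence
#'
#' Keeps detections with confidence greater than or equal to the threshold
#' (the default 0.95 reads the "95% minimum" rule as inclusive).
#'
#' @param detections data frame with a \code{confidence} column.
#' @param threshold minimum confidence in \[0, 1\], default 0.95.
#' @return The filtered data frame (possibly empty).
#' @export
filter_by_confidence <- function(detections, threshold = 0.95) {
  stopifnot(threshold >= 0, threshold <= 1)
  detections[detections$confidence >= threshold, , drop = FALSE]
}

#' Drain region specification
#'
#' Regions of each camera's image where submerged drains can masquerade as
#' animals under a rough water surface. Detections whose box centre falls
#' inside a region are passed to the region's classifier predicate;
#' detections outside the regions are never touched.
#'
#' @param camera_id "left" or "right".
#' @param polygon n x 2 matrix, image coordinates (px).
#' @param classifier function(detections_df) -> logical vector, TRUE for
#'   detections judged to be drains. \code{\link{drain_classifier_never}}
#'   is a no-op stand-in for use when no classifier is available;
#'   \code{\link{drain_classifier_oracle}} looks detections up in a
#'   synthetic truth table.
#' @return Object of class \code{drain_region}.
#' @export
drain_region <- function(camera_id, polygon, classifier = NULL) {
  structure(list(camera_id = camera_id, polygon = polygon, classifier = classifier),
            class = "drain_region")
}

#' @rdname drain_region
#' @export
drain_classifier_never <- function() function(detections) rep(FALSE, nrow(detections))

#' @rdname drain_region
#' @param truth_ids detection ids known (from a synthetic truth table) to be
#'   drain artifacts.
#' @export
drain_classifier_oracle <- function(truth_ids) {
  force(truth_ids)
  function(detections) detections$detection_id %in% truth_ids
}

#' Remove drain false positives
#'
#' @param detections raw detection data frame (columns \code{camera_id},
#'   \code{x1..y4}; a \code{detection_id} column is required only by the
#'   oracle classifier).
#' @param drain_regions list of \code{\link{drain_region}} objects.
#' @return Detections with classified-drain rows removed.
#' @export
filter_drain_false_positives <- function(detections, drain_regions) {
  if (!length(drain_regions) || !nrow(detections)) return(detections)
  cx <- rowMeans(detections[, c("x1", "x2", "x3", "x4")])
  cy <- rowMeans(detections[, c("y1", "y2", "y3", "y4")])
  drop <- rep(FALSE, nrow(detections))
  for (reg in drain_regions) {
    sel <- detections$camera_id == reg$camera_id &
      in_polygon(reg$polygon, cbind(cx, cy))
    if (!any(sel)) next
    if (is.null(reg$classifier))
      stop("filter_drain_false_positives: drain region for camera '",
           reg$camera_id, "' has no classifier configured")
    drop[sel] <- drop[sel] | reg$classifier(detections[sel, , drop = FALSE])
  }
  detections[!drop, , drop = FALSE]
}

#' Mutual-best IoU association of cross-camera boxes
#'
#' A pair (i, j) is matched iff their IoU is positive, j is i's best
#' right-camera match and i is j's best left-camera match. IoU ties are
#' broken by the smaller detection index.
#'
#' @param left_quads,right_quads lists of world quadrilaterals (4 x 2).
#' @return List with \code{pairs} (data frame \code{left}, \code{right},
#'   \code{iou}) and logical vectors \code{left_matched},
#'   \code{right_matched}.
#' @export
associate_mutual_best <- function(left_quads, right_quads) {
  nl <- length(left_quads); nr <- length(right_quads)
  pairs <- data.frame(left = integer(0), right = integer(0), iou = numeric(0))
  if (nl && nr) {
    iou <- matrix(0, nl, nr)
    for (i in seq_len(nl)) for (j in seq_len(nr))
      iou[i, j] <- polygon_iou(left_quads[[i]], right_quads[[j]])
    best_r <- apply(iou, 1, which.max)  # ties -> smallest index
    best_l <- apply(iou, 2, which.max)
    for (i in seq_len(nl)) {
      j <- best_r[i]
      if (iou[i, j] > 0 && best_l[j] == i)
        pairs <- rbind(pairs, data.frame(left = i, right = j, iou = iou[i, j]))
    }
  }
  list(pairs = pairs,
       left_matched = seq_len(nl) %in% pairs$left,
       right_matched = seq_len(nr) %in% pairs$right)
}

#' Meshing weights for a world point in the overlap strip
#'
#' For a detection at \code{u}, the nearest projected camera boundary
#' \eqn{b_n} (evaluated at u's y) defines the "near" camera — the one that
#' sees the detection closest to its field-of-view edge, hence most
#' obliquely. With \eqn{d_b} the x-distance from u to \eqn{b_n} and
#' \eqn{d_l} the x-distance from the midline \eqn{l_s} to \eqn{b_n}, the
#' near camera's weight is \eqn{w_n = d_b / (2 d_l)} and the far camera's
#' \eqn{w_f = 1 - w_n}: equal weights on the midline, all weight on the far
#' camera at the boundary.
#'
#' @param u length-2 world point (m).
#' @param overlap an \code{\link{compute_overlap}} result.
#' @param left,right the camera models.
#' @return List with \code{w_n}, \code{w_f}, \code{d_b}, \code{d_l} and
#'   \code{near} (the near camera's id).
#' @export
mesh_weights <- function(u, overlap, left, right) {
  bl <- fov_boundary_x_at(left, u[2])
  br <- fov_boundary_x_at(right, u[2])
  if (abs(u[1] - bl) <= abs(u[1] - br)) {
    b_n <- bl; near <- "left"
  } else {
    b_n <- br; near <- "right"
  }
  d_b <- abs(u[1] - b_n)
  d_l <- abs(overlap$l_s - b_n)
  if (d_l <= .Machine$double.eps)
    stop("mesh_weights: degenerate geometry, midline coincides with a camera boundary")
  w_n <- min(d_b / (2 * d_l), 0.5)
  list(w_n = w_n, w_f = 1 - w_n, d_b = d_b, d_l = d_l, near = near)
}

#' Read a raw detection table
#'
#' Delimited text with header. Two dialects are auto-detected: explicit
#' vertices (\code{t_s, camera_id, x1, y1, ..., x4, y4, confidence}) or
#' axis-aligned boxes (\code{t_s, camera_id, x, y, w, h, confidence}),
#' which are expanded to vertices.
#'
#' @param path file path.
#' @return Data frame with columns \code{detection_id, t, camera_id,
#'   x1..y4, confidence}.
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("x", "y", "w", "h") %in% names(d))) {
    d$x1 <- d$x;        d$y1 <- d$y
    d$x2 <- d$x + d$w;  d$y2 <- d$y
    d$x3 <- d$x + d$w;  d$y3 <- d$y + d$h
    d$x4 <- d$x;        d$y4 <- d$y + d$h
  }
  need <- c("t_s", "camera_id", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)), "confidence")
  if (!all(need %in% names(d)))
    stop("read_detections: unrecognized detection table dialect in ", path)
  out <- d[, need]
  names(out)[1] <- "t"
  if (!"detection_id" %in% names(d)) out$detection_id <- seq_len(nrow(out))
  else out$detection_id <- d$detection_id
  out
}

#' Write a meshed detection table
#'
#' @param meshed output of \code{\link{mesh_detections}}.
#' @param path output path (CSV).
#' @export
write_meshed <- function(meshed, path) {
  out <- meshed
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_sig)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mesh raw two-camera detections into world-frame detections
#'
#' Runs the full per-frame meshing chain: confidence filter, drain
#' false-positive filter, world-frame box projection, mutual-best IoU
#' pairing and weighted centroid meshing. Unpaired detections pass through
#' with weight 1. Meshed centroids falling outside the habitat polygon are
#' clamped to the nearest boundary point (counted in the
#' \code{n_clamped} attribute).
#'
#' @param detections raw detection data frame (see
#'   \code{\link{read_detections}}).
#' @param left,right camera models.
#' @param overlap output of \code{\link{compute_overlap}}.
#' @param habitat_polygon habitat perimeter polygon (m).
#' @param confidence_threshold minimum detector confidence (default 0.95).
#' @param drain_regions optional list of \code{\link{drain_region}}.
#' @return Data frame with columns \code{t, u_x, u_y, n_sources, w_n, iou,
#'   near_camera, detection_id} (id of the near/primary source detection).
#' @export
mesh_detections <- function(detections, left, right, overlap, habitat_polygon,
                            confidence_threshold = 0.95, drain_regions = NULL) {
  d <- filter_by_confidence(detections, confidence_threshold)
  d <- filter_drain_false_positives(d, drain_regions)
  empty <- data.frame(t = numeric(0), u_x = numeric(0), u_y = numeric(0),
                      n_sources = integer(0), w_n = numeric(0), iou = numeric(0),
                      near_camera = character(0), detection_id = integer(0))
  if (!nrow(d)) return(empty)
  cams <- list(left = left, right = right)
  strip <- overlap$strip

  # project all boxes at once, per camera
  wq <- matrix(NA_real_, nrow(d), 8)   # world-frame vertices x1,y1..x4,y4
  for (cid in c("left", "right")) {
    sel <- which(d$camera_id == cid)
    if (!length(sel)) next
    H <- cams[[cid]]$H
    for (v in 1:4) {
      pv <- project_points(H, cbind(d[[paste0("x", v)]][sel], d[[paste0("y", v)]][sel]))
      wq[sel, 2 * v - 1] <- pv[, 1]; wq[sel, 2 * v] <- pv[, 2]
    }
  }
  # drop self-intersecting projections (vectorized diagonal-edge crossing test)
  crs <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  x1 <- wq[, 1]; y1 <- wq[, 2]; x2 <- wq[, 3]; y2 <- wq[, 4]
  x3 <- wq[, 5]; y3 <- wq[, 6]; x4 <- wq[, 7]; y4 <- wq[, 8]
  bow1 <- crs(x3, y3, x4, y4, x1, y1) * crs(x3, y3, x4, y4, x2, y2) < 0 &
          crs(x1, y1, x2, y2, x3, y3) * crs(x1, y1, x2, y2, x4, y4) < 0
  bow2 <- crs(x4, y4, x1, y1, x2, y2) * crs(x4, y4, x1, y1, x3, y3) < 0 &
          crs(x2, y2, x3, y3, x4, y4) * crs(x2, y2, x3, y3, x1, y1) < 0
  bad <- bow1 | bow2
  if (any(bad)) {
    warning("mesh_detections: dropped ", sum(bad),
            " detections with self-intersecting projections")
    d <- d[!bad, , drop = FALSE]; wq <- wq[!bad, , drop = FALSE]
  }
  if (!nrow(d)) return(empty)
  cx <- rowMeans(wq[, c(1, 3, 5, 7), drop = FALSE])
  cy <- rowMeans(wq[, c(2, 4, 6, 8), drop = FALSE])

  # interpolated boundary-x lookups (the projected borders are near-vertical
  # lines; their x varies slowly with y)
  ygrid <- seq(min(habitat_polygon[, 2]) - 1, max(habitat_polygon[, 2]) + 1, by = 0.1)
  bl_fun <- approxfun(ygrid, vapply(ygrid, function(y) fov_boundary_x_at(left, y),
                                    numeric(1)), rule = 2)
  br_fun <- approxfun(ygrid, vapply(ygrid, function(y) fov_boundary_x_at(right, y),
                                    numeric(1)), rule = 2)

  n <- nrow(d)
  o_t <- numeric(n); o_ux <- numeric(n); o_uy <- numeric(n)
  o_ns <- integer(n); o_wn <- numeric(n); o_iou <- numeric(n)
  o_near <- character(n); o_id <- integer(n); n_out <- 0L
  emit <- function(t, ux, uy, ns, wn, iou, near, id) {
    n_out <<- n_out + 1L
    o_t[n_out] <<- t; o_ux[n_out] <<- ux; o_uy[n_out] <<- uy
    o_ns[n_out] <<- ns; o_wn[n_out] <<- wn; o_iou[n_out] <<- iou
    o_near[n_out] <<- near; o_id[n_out] <<- id
  }

  quad_of <- function(i) matrix(wq[i, ], ncol = 2, byrow = TRUE)
  near_strip <- cx >= strip[1] - 2.5 & cx <= strip[2] + 2.5
  is_left <- d$camera_id == "left"

  for (fr in split(seq_len(n), d$t)) {
    li <- fr[is_left[fr]]; ri <- fr[!is_left[fr]]
    # IoU only for candidate pairs near the strip with nearby centroids
    nl <- length(li); nr_ <- length(ri)
    iou <- matrix(0, nl, nr_)
    if (nl && nr_) {
      for (a in seq_len(nl)) {
        if (!near_strip[li[a]]) next
        for (b in seq_len(nr_)) {
          if (!near_strip[ri[b]]) next
          if (abs(cx[li[a]] - cx[ri[b]]) > 3 || abs(cy[li[a]] - cy[ri[b]]) > 3) next
          iou[a, b] <- polygon_iou(quad_of(li[a]), quad_of(ri[b]))
        }
      }
    }
    lm <- logical(nl); rm_ <- logical(nr_)
    if (nl && nr_ && any(iou > 0)) {
      best_r <- apply(iou, 1, which.max)
      best_l <- apply(iou, 2, which.max)
      for (a in seq_len(nl)) {
        b <- best_r[a]
        if (iou[a, b] > 0 && best_l[b] == a) {
          lm[a] <- TRUE; rm_[b] <- TRUE
          i <- li[a]; j <- ri[b]
          u0 <- c((cx[i] + cx[j]) / 2, (cy[i] + cy[j]) / 2)
          if (u0[1] >= strip[1] && u0[1] <= strip[2]) {
            bl <- bl_fun(u0[2]); br <- br_fun(u0[2])
            if (abs(u0[1] - bl) <= abs(u0[1] - br)) {
              b_n <- bl; near <- "left"; ci <- i; cj <- j
            } else {
              b_n <- br; near <- "right"; ci <- j; cj <- i
            }
            d_l <- abs(overlap$l_s - b_n)
            w_n <- min(abs(u0[1] - b_n) / (2 * d_l), 0.5)
            emit(d$t[i], w_n * cx[ci] + (1 - w_n) * cx[cj],
                 w_n * cy[ci] + (1 - w_n) * cy[cj],
                 2L, w_n, iou[a, b], near, d$detection_id[ci])
          } else {
            emit(d$t[i], u0[1], u0[2], 2L, 0.5, iou[a, b],
                 if (u0[1] < strip[1]) "right" else "left", d$detection_id[i])
          }
        }
      }
    }
    # unpaired detections pass through with weight 1, sourced by their camera
    for (a in which(!lm)) {
      i <- li[a]
      emit(d$t[i], cx[i], cy[i], 1L, 1, 0, "left", d$detection_id[i])
    }
    for (b in which(!rm_)) {
      j <- ri[b]
      emit(d$t[j], cx[j], cy[j], 1L, 1, 0, "right", d$detection_id[j])
    }
  }

  res <- data.frame(t = o_t[seq_len(n_out)], u_x = o_ux[seq_len(n_out)],
                    u_y = o_uy[seq_len(n_out)], n_sources = o_ns[seq_len(n_out)],
                    w_n = o_wn[seq_len(n_out)], iou = o_iou[seq_len(n_out)],
                    near_camera = o_near[seq_len(n_out)],
                    detection_id = o_id[seq_len(n_out)])
  # clamp meshed centroids into the habitat polygon (vectorized test)
  inside <- in_polygon(habitat_polygon, cbind(res$u_x, res$u_y))
  n_clamped <- sum(!inside)
  if (n_clamped) {
    for (i in which(!inside)) {
      p <- clamp_to_polygon(habitat_polygon, c(res$u_x[i], res$u_y[i]))
      res$u_x[i] <- p[1]; res$u_y[i] <- p[2]
    }
    message("mesh_detections: clamped ", n_clamped,
            " meshed centroids into the habitat polygon")
  }
  res <- res[order(res$t), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_clamped") <- n_clamped
  res
}
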