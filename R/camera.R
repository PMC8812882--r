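# Camera calibration and world-frame projection.
#
# World-frame convention: origin at the habitat's left-near corner, x along
# the long (33.5 m) axis increasing toward the right camera, y along the
# 12.2 m width. All world coordinates are in metres; image coordinates in
# pixels.

#' Estimate a planar homography with the normalized DLT
#'
#' Direct Linear Transform with Hartley normalization: each point set is
#' translated so its centroid is at the origin and scaled so the mean
#' distance from the origin is \eqn{\sqrt{2}}, the 2n x 9 design matrix is
#' solved by SVD, and the normalization is undone. The result is scaled so
#' that \code{H[3,3] = 1} (falling back to unit Frobenius norm when that
#' entry is numerically zero).
#'
#' @param image_points n x 2 matrix of image coordinates (px), n >= 4.
#' @param world_points n x 2 matrix of world coordinates (m).
#' @return 3 x 3 homography mapping homogeneous image points to world points.
#' @export
estimate_homography_dlt <- function(image_points, world_points) {
  image_points <- as.matrix(image_points); world_points <- as.matrix(world_points)
  n <- nrow(image_points)
  if (n < 4 || nrow(world_points) != n)
    stop("estimate_homography_dlt: need >= 4 matched correspondences")

  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = T, p = cbind(p, 1) %*% t(T))
  }
  # a point set collapsed onto a single line cannot pin down a homography
  check_spread <- function(p, what) {
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1))
      stop("estimate_homography_dlt: degenerate configuration, all ", what,
           " points are collinear: ",
           paste(apply(round(p, 3), 1, paste, collapse = ","), collapse = "; "))
  }
  check_spread(image_points, "image")
  check_spread(world_points, "world")
  ni <- normalize(image_points)
  nw <- normalize(world_points)

  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ni$p[i, ]; xp <- nw$p[i, ]
    A[2 * i - 1, ] <- c(0, 0, 0, -xp[3] * x, xp[2] * x)
    A[2 * i, ]     <- c(xp[3] * x, 0, 0, 0, -xp[1] * x)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-10) {
    stop("estimate_homography_dlt: degenerate correspondence configuration ",
         "(rank-deficient design matrix); check for collinear world points: ",
         paste(apply(round(world_points, 3), 1, paste, collapse = ","), collapse = "; "))
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nw$T) %*% Hn %*% ni$T
  if (abs(H[3, 3]) > 1e-8 * max(abs(H))) H <- H / H[3, 3] else H <- H / sqrt(sum(H^2))
  H
}

#' Project image points into the world frame
#'
#' Applies the homogeneous transform \code{H} and dehomogenizes.
#'
#' @param H 3 x 3 homography.
#' @param points n x 2 matrix (or length-2 vector) of image points.
#' @return n x 2 matrix of world points, input order preserved.
#' @export
project_points <- function(H, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  P <- cbind(points, 1) %*% t(H)
  w <- P[, 3]
  if (any(abs(w) < 1e-12))
    stop("project_points: point maps to the plane at infinity (w ~ 0)")
  cbind(P[, 1] / w, P[, 2] / w)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_quad <- function(q) {
  # a quadrilateral is simple iff its two pairs of opposite edges don't cross
  !(segments_intersect(q[1, ], q[2, ], q[3, ], q[4, ]) ||
      segments_intersect(q[2, ], q[3, ], q[4, ], q[1, ]))
}

#' Project a bounding box into the world frame
#'
#' Projects the four vertices with \code{\link{project_points}} and returns
#' the world quadrilateral with its centroid (vertex mean). Boxes whose
#' projection self-intersects are rejected (returns \code{NULL} with a
#' warning) and should be dropped by the caller.
#'
#' @param H 3 x 3 homography.
#' @param bbox 4 x 2 matrix of image vertices in consistent winding order.
#' @return List with \code{quad} (4 x 2 world matrix) and \code{centroid}
#'   (length-2), or \code{NULL} for a self-intersecting projection.
#' @export
project_box <- function(H, bbox) {
  q <- project_points(H, bbox)
  if (!is_simple_quad(q)) {
    warning("project_box: self-intersecting projected quadrilateral; detection dropped")
    return(NULL)
  }
  list(quad = q, centroid = colMeans(q))
}

#' Construct a calibrated camera model
#'
#' Estimates the image-to-world homography from calibration correspondences,
#' validates the reprojection error, and derives the projected field-of-view
#' border used by the meshing stage. The \code{fov_boundary_x} of a camera
#' is the world-frame x of its projected image border on the overlap side:
#' the maximum border x for the left camera and the minimum for the right
#' camera. The overlap strip between the two cameras therefore runs from
#' \code{right$fov_boundary_x} to \code{left$fov_boundary_x}.
#'
#' @param camera_id "left" or "right".
#' @param image_points,world_points calibration correspondences (n >= 4).
#' @param image_size c(width, height) in px.
#' @param world_position c(x, y) horizontal camera location (m).
#' @param height_above_water camera height above the water surface (m).
#' @param max_reproj_error calibration tolerance (m), default 0.05.
#' @return Object of class \code{camera_model}.
#' @export
camera_model <- function(camera_id, image_points, world_points, image_size,
                         world_position, height_above_water,
                         max_reproj_error = 0.05) {
  camera_id <- match.arg(camera_id, c("left", "right"))
  H <- estimate_homography_dlt(image_points, world_points)
  if (abs(det(H)) <= 0) stop("camera_model: homography is singular")
  reproj <- project_points(H, image_points)
  err <- sqrt(rowSums((reproj - as.matrix(world_points))^2))
  if (max(err) > max_reproj_error)
    stop(sprintf("camera_model(%s): calibration reprojection error %.3f m exceeds %.3f m",
                 camera_id, max(err), max_reproj_error))

  # densely sample the image border and project it to the world frame
  w <- image_size[1]; h <- image_size[2]
  m <- 50
  edge <- function(a, b) cbind(seq(a[1], b[1], length.out = m), seq(a[2], b[2], length.out = m))
  border_px <- rbind(edge(c(0, 0), c(w, 0)), edge(c(w, 0), c(w, h)),
                     edge(c(w, h), c(0, h)), edge(c(0, h), c(0, 0)))
  border_world <- project_points(H, border_px)
  fov_boundary_x <- if (camera_id == "left") max(border_world[, 1]) else min(border_world[, 1])

  structure(list(camera_id = camera_id, H = H, H_inv = solve(H),
                 image_size = image_size, world_position = world_position,
                 height_above_water = height_above_water,
                 border_world = border_world,
                 fov_boundary_x = fov_boundary_x,
                 reproj_error = max(err)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'>\n", x$camera_id))
  cat(sprintf("  position (%.2f, %.2f) m, height %.2f m\n",
              x$world_position[1], x$world_position[2], x$height_above_water))
  cat(sprintf("  fov boundary x = %.3f m, calibration error %.4f m\n",
              x$fov_boundary_x, x$reproj_error))
  invisible(x)
}

#' Field-of-view boundary x at a given world y
#'
#' The projected image border is generally not parallel to the world y axis;
#' the meshing weights use the boundary's x at the detection's y. The border
#' polyline is intersected with the horizontal line at \code{y}; the extreme
#' crossing on the overlap side is returned. Falls back to the camera's
#' overall \code{fov_boundary_x} when \code{y} is outside the border's span.
#'
#' @param camera a \code{camera_model}.
#' @param y world y (m).
#' @return World x of the boundary at this y (m).
#' @export
fov_boundary_x_at <- function(camera, y) {
  b <- camera$border_world
  n <- nrow(b)
  xs <- numeric(0)
  for (i in seq_len(n)) {
    p <- b[i, ]; q <- b[if (i == n) 1 else i + 1, ]
    if ((p[2] - y) * (q[2] - y) <= 0 && p[2] != q[2]) {
      t <- (y - p[2]) / (q[2] - p[2])
      xs <- c(xs, p[1] + t * (q[1] - p[1]))
    }
  }
  if (!length(xs)) return(camera$fov_boundary_x)
  if (camera$camera_id == "left") max(xs) else min(xs)
}

#' Overlap geometry of a camera pair
#'
#' The midline \eqn{l_s} is the vertical world line halfway between the two
#' camera placements (\eqn{l_s = x_{mid}}); the overlap strip runs from the
#' right camera's projected boundary to the left camera's.
#'
#' @param left,right \code{camera_model} objects with matching ids.
#' @return Object of class \code{overlap_geometry} with fields \code{l_s},
#'   \code{x_mid} and \code{strip = c(lo, hi)}.
#' @export
compute_overlap <- function(left, right) {
  stopifnot(inherits(left, "camera_model"), inherits(right, "camera_model"))
  if (left$camera_id != "left" || right$camera_id != "right")
    stop("compute_overlap: pass the left camera first and the right camera second")
  lo <- right$fov_boundary_x; hi <- left$fov_boundary_x
  if (!(lo < hi))
    stop(sprintf("compute_overlap: fields of view do not overlap (%.2f >= %.2f)", lo, hi))
  x_mid <- mean(c(left$world_position[1], right$world_position[1]))
  if (x_mid < lo || x_mid > hi)
    stop("compute_overlap: camera midline falls outside the overlap strip")
  structure(list(l_s = x_mid, x_mid = x_mid, strip = c(lo, hi)),
            class = "overlap_geometry")
}

#' @export
print.overlap_geometry <- function(x, ...) {
  cat(sprintf("<overlap_geometry> l_s = %.3f m, strip [%.3f, %.3f] m\n",
              x$l_s, x$strip[1], x$strip[2]))
  invisible(x)
}

#' Read calibration correspondences
#'
#' Delimited text with columns \code{camera_id, u_px, v_px, x_m, y_m}.
#'
#' @param path file path.
#' @return Data frame of correspondences.
#' @export
read_calibration <- function(path) {
  cal <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "u_px", "v_px", "x_m", "y_m")
  if (!all(need %in% names(cal)))
    stop("read_calibration: expected columns ", paste(need, collapse = ", "))
  cal
}

#' Serialize / restore a camera model as JSON
#'
#' The homography is stored row-major as 9 numbers.
#'
#' @param camera a \code{camera_model}.
#' @param path output (input) JSON path.
#' @return \code{write_camera_json}: the path, invisibly.
#'   \code{read_camera_json}: a \code{camera_model}.
#' @export
write_camera_json <- function(camera, path) {
  obj <- list(camera_id = camera$camera_id,
              H = as.vector(t(camera$H)),
              image_size = camera$image_size,
              world_position = camera$world_position,
              height_above_water = camera$height_above_water,
              border_world = camera$border_world,
              fov_boundary_x = camera$fov_boundary_x,
              reproj_error = camera$reproj_error)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(obj$H, 3, 3, byrow = TRUE)
  structure(list(camera_id = obj$camera_id, H = H, H_inv = solve(H),
                 image_size = obj$image_size,
                 world_position = obj$world_position,
                 height_above_water = obj$height_above_water,
                 border_world = matrix(unlist(obj$border_world), ncol = 2),
                 fov_boundary_x = obj$fov_boundary_x,
                 reproj_error = obj$reproj_error),
            class = "camera_model")
}
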