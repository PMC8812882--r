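# Planar polygon utilities shared by the camera, meshing and mapping stages.
# Polygons are n x 2 matrices of (x, y) vertices in metres, implicitly closed.

# round a numeric vector to 6 significant digits (NA-safe), for the fixed
# float formatting of text artifacts
format_sig <- function(x, digits = 6) {
  sel <- !is.na(x)
  x[sel] <- as.numeric(sprintf("%.*g", digits, x[sel]))
  x
}

#' Signed and absolute polygon area
#'
#' Shoelace formula. Positive signed area means counter-clockwise winding.
#'
#' @param poly n x 2 numeric matrix of vertices (implicitly closed).
#' @return Signed area in squared input units.
#' @export
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @rdname polygon_area_signed
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Test whether points fall inside a polygon
#'
#' Thin wrapper around \code{mgcv::in.out}. Points exactly on the boundary
#' are not guaranteed to be classified as inside.
#'
#' @param poly n x 2 vertex matrix.
#' @param pts m x 2 matrix (or length-2 vector) of query points.
#' @return Logical vector of length m.
#' @export
in_polygon <- function(poly, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(TRUE)
  nxt <- c(2:n, 1)
  nnx <- c(3:n, 1, 2)
  e1 <- poly[nxt, ] - poly
  e2 <- poly[nnx, ] - poly[nxt, ]
  cr <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  all(cr >= -1e-12) || all(cr <= 1e-12)
}

# Sutherland-Hodgman clipping of a subject polygon by a convex clip polygon.
# Returns an m x 2 matrix (possibly 0 rows).
clip_polygon <- function(subject, clip) {
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    # inside = left of directed edge a -> b (CCW clip polygon)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    sv <- vapply(seq_len(n), function(j) side(inp[j, ]), numeric(1))
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      cur <- inp[j, ]; nxt <- inp[k, ]
      cin <- sv[j] >= -1e-12; nin <- sv[k] >= -1e-12
      if (cin) out <- rbind(out, cur)
      if (xor(cin, nin)) {
        t <- sv[j] / (sv[j] - sv[k])
        out <- rbind(out, cur + t * (nxt - cur))
      }
    }
  }
  out
}

#' Intersection-over-union of two simple polygons
#'
#' Area of the intersection divided by the area of the union. Used to
#' identify conflicting cross-camera bounding boxes. Non-convex inputs are
#' replaced by their convex hulls (projected bounding boxes are convex in
#' all non-degenerate configurations; the hull fallback is a guard).
#'
#' @param a,b polygon vertex matrices (n x 2).
#' @return IoU in \[0, 1\]; 0 when the polygons are disjoint.
#' @export
polygon_iou <- function(a, b) {
  area_a <- polygon_area(a); area_b <- polygon_area(b)
  if (area_a <= 0 || area_b <= 0) stop("polygon_iou: zero-area polygon")
  if (!is_convex(a)) a <- a[chull(a[, 1], a[, 2]), , drop = FALSE]
  if (!is_convex(b)) b <- b[chull(b[, 1], b[, 2]), , drop = FALSE]
  inter <- clip_polygon(a, b)
  ai <- if (nrow(inter) >= 3) polygon_area(inter) else 0
  ai / (area_a + area_b - ai)
}

# Nearest point on segment ab to p.
nearest_on_segment <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  a + t * ab
}

#' Clamp a point into a polygon
#'
#' Points already inside are returned unchanged; outside points are moved
#' to the nearest point on the polygon boundary.
#'
#' @param poly polygon vertex matrix.
#' @param p length-2 point.
#' @return length-2 point inside or on the boundary of \code{poly}.
#' @export
clamp_to_polygon <- function(poly, p) {
  if (in_polygon(poly, p)) return(p)
  n <- nrow(poly)
  best <- NULL; bd <- Inf
  for (i in seq_len(n)) {
    q <- nearest_on_segment(p, poly[i, ], poly[if (i == n) 1 else i + 1, ])
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; best <- q }
  }
  best
}

# Distance along direction `dir` (unit) from interior point p to the first
# polygon boundary crossing. Inf if no crossing (should not happen for
# bounded polygons).
ray_exit_distance <- function(poly, p, dir) {
  n <- nrow(poly)
  tmin <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    e <- b - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-14) next
    rhs <- a - p
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    s <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (t >= 0 && s >= -1e-12 && s <= 1 + 1e-12) tmin <- min(tmin, t)
  }
  tmin
}

#' Axis-aligned rectangle as a polygon
#'
#' Convenience constructor used for the default habitat perimeter.
#'
#' @param width,height rectangle dimensions (m).
#' @param origin lower-left corner, default (0, 0).
#' @return 4 x 2 vertex matrix, counter-clockwise.
#' @export
rect_polygon <- function(width, height, origin = c(0, 0)) {
  matrix(c(origin[1], origin[2],
           origin[1] + width, origin[2],
           origin[1] + width, origin[2] + height,
           origin[1], origin[2] + height),
         ncol = 2, byrow = TRUE)
}
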