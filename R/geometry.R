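#' Pixel-space geometry for kernel fragment sizing
#'
#' Polygons are plain two-column numeric matrices of `(x, y)` vertices in
#' pixels, implicitly closed. Coordinates follow the image convention:
#' origin at the top-left, x rightward, y downward. Boxes are numeric
#' vectors `c(xmin, ymin, xmax, ymax)`.
#'
#' @name geometry
#' @keywords internal
NULL

#' Validate and normalise a polygon
#'
#' Coerces `p` to a two-column matrix, drops consecutive duplicate
#' vertices, and checks the polygon invariants: at least three vertices,
#' finite coordinates, nonzero area.
#'
#' @param p A two-column matrix (or coercible) of `(x, y)` vertex
#'   coordinates in pixels.
#' @return The cleaned vertex matrix.
#' @export
as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stopf("polygon must have two columns (x, y)")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stopf("polygon has non-finite coordinates")
  # drop consecutive duplicates (closing duplicate included)
  n <- nrow(p)
  if (n >= 2L) {
    keep <- c(TRUE, rowSums(abs(p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])) > 0)
    p <- p[keep, , drop = FALSE]
    n <- nrow(p)
    if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  }
  if (nrow(p) < 3L) stopf("polygon needs at least 3 distinct vertices")
  if (abs(polygon_area(p)) < .Machine$double.eps) stopf("polygon has zero area")
  p
}

# Shoelace signed area (positive = counter-clockwise in coordinate order).
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Convex hull of a polygon
#'
#' @param p Polygon vertices (see [as_polygon()]).
#' @return Hull vertices in counter-clockwise order (positive shoelace
#'   area in the stored coordinates), collinear points dropped.
#' @examples
#' convex_hull(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, 5)))
#' @export
convex_hull <- function(p) {
  p <- as_polygon(p)
  u <- unique(p)
  idx <- grDevices::chull(u[, 1L], u[, 2L])
  if (length(idx) < 3L) stopf("degenerate geometry: fewer than 3 non-collinear vertices")
  h <- u[idx, , drop = FALSE]
  if (polygon_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  if (abs(polygon_area(h)) < .Machine$double.eps)
    stopf("degenerate geometry: hull has zero area")
  h
}

#' Minimum-area rotated bounding rectangle
#'
#' Computes the smallest-area rectangle enclosing a polygon by rotating
#' calipers over its convex hull: the optimal rectangle has one side
#' flush with a hull edge, so each hull edge direction is tried and the
#' extent of the hull along that direction and its normal gives a
#' candidate rectangle. The minor axis (`side_b`) of this rectangle is
#' the fragment size that governs passage through a sieve screen.
#'
#' @param p Polygon vertices.
#' @return A list of class `kps_rotated_rect` with fields `center`
#'   (`c(x, y)` pixels), `side_a`, `side_b` (pixels, `side_a >= side_b`),
#'   and `angle` (degrees of the `side_a` direction from the +x axis, in
#'   `[0, 180)`).
#' @examples
#' r <- min_area_rect(rbind(c(0, 0), c(10, 0), c(10, 4), c(0, 4)))
#' r$side_b  # 4: the minor axis
#' @export
min_area_rect <- function(p) {
  h <- convex_hull(p)
  m <- nrow(h)
  e <- h[c(2:m, 1L), , drop = FALSE] - h  # edge vectors
  len <- sqrt(rowSums(e^2))
  d <- e / len                            # unit edge directions
  best <- NULL
  best_area <- Inf
  best_minor <- Inf
  for (i in seq_len(m)) {
    dx <- d[i, 1L]; dy <- d[i, 2L]
    u <- h[, 1L] * dx + h[, 2L] * dy      # projection onto edge dir
    v <- -h[, 1L] * dy + h[, 2L] * dx     # projection onto normal
    w <- max(u) - min(u)
    ht <- max(v) - min(v)
    area <- w * ht
    # minimum-area rectangles can tie exactly (symmetric polygons admit
    # several optimal orientations with different aspect); break ties
    # toward the smaller minor axis so the reported width is stable
    # under rigid motion and closest to the sieve-relevant dimension
    better <- area < best_area * (1 - 1e-9) ||
      (area <= best_area * (1 + 1e-9) && min(w, ht) < best_minor)
    if (better) {
      best_area <- min(area, best_area)
      best_minor <- min(w, ht)
      cu <- (max(u) + min(u)) / 2
      cv <- (max(v) + min(v)) / 2
      best <- list(
        center = c(cu * dx - cv * dy, cu * dy + cv * dx),
        w = w, h = ht, theta = atan2(dy, dx)
      )
    }
  }
  side_a <- max(best$w, best$h)
  side_b <- min(best$w, best$h)
  ang <- best$theta * 180 / pi
  if (best$h > best$w) ang <- ang + 90   # report the long-side direction
  ang <- ang %% 180
  structure(
    list(center = unname(best$center), side_a = side_a, side_b = side_b,
         angle = ang),
    class = "kps_rotated_rect"
  )
}

#' @export
print.kps_rotated_rect <- function(x, ...) {
  cat(sprintf(
    "rotated rect: center (%.2f, %.2f), sides %.2f x %.2f px, angle %.1f deg\n",
    x$center[1L], x$center[2L], x$side_a, x$side_b, x$angle))
  invisible(x)
}

#' Axis-aligned bounding box of a polygon
#'
#' The box spanned by the coordinate extremes of the vertices.
#'
#' @param p Polygon vertices.
#' @return Numeric `c(xmin, ymin, xmax, ymax)` in pixels.
#' @export
box_from_polygon <- function(p) {
  p <- as_polygon(p)
  c(min(p[, 1L]), min(p[, 2L]), max(p[, 1L]), max(p[, 2L]))
}

as_box <- function(b) {
  b <- as.numeric(b)
  if (length(b) != 4L || !all(is.finite(b))) stopf("box must be c(xmin, ymin, xmax, ymax)")
  if (b[3L] < b[1L] || b[4L] < b[2L]) stopf("box has xmax < xmin or ymax < ymin")
  b
}

box_area <- function(b) (b[3L] - b[1L]) * (b[4L] - b[2L])

#' Intersection-over-union of two axis-aligned boxes
#'
#' @param a,b Boxes as `c(xmin, ymin, xmax, ymax)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  aa <- box_area(a); ab <- box_area(b)
  if (aa == 0 && ab == 0) stopf("IoU undefined: both boxes have zero area")
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (aa + ab - inter)
}

# Even-odd point-in-polygon test for a vector of query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  vx <- poly[, 1L]; vy <- poly[, 2L]
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- vx[k]; y2 <- vy[k]
    crosses <- ((y2 > py) != (y1 > py))
    if (any(crosses)) {
      xint <- x2 + (py[crosses] - y2) * (x1 - x2) / (y1 - y2)
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

# Rasterize a polygon on the integer pixel grid: a pixel belongs to the
# mask iff its center (i + 0.5, j + 0.5) lies inside the polygon.
rasterize_polygon <- function(p, xr, yr) {
  cx <- seq(floor(xr[1L]), ceiling(xr[2L])) + 0.5
  cy <- seq(floor(yr[1L]), ceiling(yr[2L])) + 0.5
  g <- expand.grid(x = cx, y = cy)
  points_in_polygon(g$x, g$y, p)
}

#' Intersection-over-union of two polygon masks
#'
#' Both polygons are rasterized on the shared integer pixel grid
#' (pixel-center containment at native resolution) and the IoU of the
#' two binary masks is returned, matching how instance-segmentation
#' benchmarks score masks at the pixel level.
#'
#' @param a,b Polygon vertex matrices.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  a <- as_polygon(a); b <- as_polygon(b)
  xr <- range(c(a[, 1L], b[, 1L]))
  yr <- range(c(a[, 2L], b[, 2L]))
  ma <- rasterize_polygon(a, xr, yr)
  mb <- rasterize_polygon(b, xr, yr)
  uni <- sum(ma | mb)
  if (uni == 0L) stopf("IoU undefined: both polygons rasterize to empty masks")
  sum(ma & mb) / uni
}

#' Convert a pixel length to millimetres
#'
#' The imaging rig fixes the resolution at 20 pixels per millimetre
#' (0.05 mm per pixel); other scales can be supplied per image.
#'
#' @param length_px Non-negative length(s) in pixels.
#' @param px_per_mm Pixels per millimetre, strictly positive. Default 20.
#' @return Length(s) in millimetres.
#' @examples
#' px_to_mm(95)   # 4.75 mm, the sieve threshold
#' px_to_mm(200)  # 10 mm = 1 cm
#' @export
px_to_mm <- function(length_px, px_per_mm = 20) {
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0)
    stopf("px_per_mm must be a single positive number")
  if (any(length_px < 0)) stopf("length_px must be non-negative")
  length_px / px_per_mm
}
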