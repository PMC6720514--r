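# Independent oracles used to check the geometry and matching code.
# These deliberately use different (slower, brute-force) algorithms
# than the implementation under test.

# Brute-force convex hull: a point is interior iff it lies strictly
# inside some triangle of other points; hull vertices are the rest.
brute_force_hull <- function(pts) {
  n <- nrow(pts)
  sgn_area <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  strictly_inside <- function(p, a, b, c) {
    s <- sgn_area(a, b, c)
    if (s == 0) return(FALSE)
    d1 <- sgn_area(p, a, b) / s
    d2 <- sgn_area(p, b, c) / s
    d3 <- sgn_area(p, c, a) / s
    d1 > 1e-12 && d2 > 1e-12 && d3 > 1e-12
  }
  keep <- rep(TRUE, n)
  tri <- utils::combn(n, 3)
  for (i in seq_len(n)) {
    for (t in seq_len(ncol(tri))) {
      idx <- tri[, t]
      if (i %in% idx) next
      if (strictly_inside(pts[i, ], pts[idx[1], ], pts[idx[2], ], pts[idx[3], ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pts[keep, , drop = FALSE]
}

# Exhaustive min-area enclosing rectangle: sweep orientations in fine
# angular steps, project the points, take the minimal extent product.
angle_sweep_rect <- function(pts, step_deg = 0.01) {
  th <- seq(0, 90, by = step_deg) * pi / 180
  px <- split(pts[, 1], seq_len(nrow(pts)))
  py <- split(pts[, 2], seq_len(nrow(pts)))
  # K x n projection matrices, reduced by pmax/pmin over vertex columns
  U <- lapply(seq_len(nrow(pts)), function(i)
    pts[i, 1] * cos(th) + pts[i, 2] * sin(th))
  V <- lapply(seq_len(nrow(pts)), function(i)
    -pts[i, 1] * sin(th) + pts[i, 2] * cos(th))
  w <- do.call(pmax, U) - do.call(pmin, U)
  h <- do.call(pmax, V) - do.call(pmin, V)
  areas <- w * h
  k <- which.min(areas)
  list(area = areas[k], side_min = min(w[k], h[k]), side_max = max(w[k], h[k]))
}

# Random convex polygon: convex hull of a gaussian point cloud.
random_convex_polygon <- function(n_points = 12, scale = 50, center = c(0, 0)) {
  pts <- cbind(stats::rnorm(n_points, center[1], scale),
               stats::rnorm(n_points, center[2], scale))
  pts[grDevices::chull(pts), , drop = FALSE]
}

rect_poly <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
}

rotate_pts <- function(p, deg, about = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(sweep(p, 2, about) %*% t(R), 2, about, `+`)
}

# Exact IoU of two axis-aligned rectangles (for the mask-IoU oracle).
exact_rect_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  area <- function(r) (r[3] - r[1]) * (r[4] - r[2])
  inter / (area(a) + area(b) - inter)
}

# Exhaustive matching: enumerate every one-to-one assignment of
# detections to ground truths (pairs must reach the IoU threshold),
# maximizing TP count and, among those, total IoU.
exhaustive_match <- function(iou, threshold) {
  ng <- nrow(iou); nd <- ncol(iou)
  best <- list(tp = 0L, total = 0)
  recurse <- function(j, used_gt, tp, total) {
    if (j > nd) {
      if (tp > best$tp || (tp == best$tp && total > best$total))
        best <<- list(tp = tp, total = total)
      return(invisible())
    }
    recurse(j + 1L, used_gt, tp, total)  # detection j unmatched
    if (ng > 0L) for (i in seq_len(ng)) {
      if (!used_gt[i] && iou[i, j] >= threshold) {
        used_gt[i] <- TRUE
        recurse(j + 1L, used_gt, tp + 1L, total + iou[i, j])
        used_gt[i] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L, 0)
  best
}

# Small square-polygon instance helper for matching tests.
box_instance <- function(xmin, ymin, xmax, ymax, score = NA_real_) {
  kernel_instance(polygon = rect_poly(xmin, ymin, xmax, ymax), score = score)
}
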