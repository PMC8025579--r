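# Planar geometry primitives on simple polygons (matrices with columns x, y,
# open rings: last vertex != first).  All coordinates are metres.

# Even-odd ray casting, vectorised over query points.  Points exactly on an
# edge may land on either side; the generator never places anything on a
# shared boundary on purpose, and the raster centre-in-polygon rule documents
# the convention.
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.point_in_polygon <- function(p, poly) {
  .points_in_polygon(p[1], p[2], poly)
}

# Signed area (shoelace); positive for counter-clockwise rings.
.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

.polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

# Uniform rejection sampling of n points inside a simple polygon.
.sample_in_polygon <- function(n, poly) {
  bb <- .polygon_bbox(poly)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    cx <- runif(m, bb["xmin"], bb["xmax"])
    cy <- runif(m, bb["ymin"], bb["ymax"])
    keep <- .points_in_polygon(cx, cy, poly)
    out <- rbind(out, cbind(cx[keep], cy[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# Perpendicular projection of point p onto segment a-b, clamped to the
# endpoints.  Returns the curvilinear parameter t in [0, 1] and the distance.
.project_on_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  list(t = t, dist = sqrt((px - qx)^2 + (py - qy)^2), x = qx, y = qy)
}

#' Population-weighted centroid of dwelling points
#'
#' The representative point of a small area, defined as the weighted
#' arithmetic mean of its dwelling locations with weights equal to the
#' residents at each dwelling.  This is the origin used for all road-network
#' distance calculations.
#'
#' @param points Numeric matrix with two columns (x, y metres), one row per
#'   dwelling.
#' @param weights Non-negative numeric vector of residents per dwelling;
#'   must contain at least one positive weight.
#' @return Numeric vector `c(x, y)`.
#' @examples
#' population_weighted_centroid(rbind(c(0, 0), c(100, 0)), c(3, 1)) # (25, 0)
#' @export
population_weighted_centroid <- function(points, weights) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("no dwelling points supplied", call. = FALSE)
  if (length(weights) != nrow(points))
    stop("one weight per dwelling point is required", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- sum(weights)
  if (w <= 0)
    stop("degenerate input: total dwelling weight is zero", call. = FALSE)
  c(x = sum(points[, 1] * weights) / w,
    y = sum(points[, 2] * weights) / w)
}
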