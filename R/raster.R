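# Raster representation of green/blue cover and its Euclidean distance
# transform.  Grids are stored as matrices indexed [ix, iy] with cell (1, 1)
# at the window's lower-left corner; the centre of cell (ix, iy) lies at
# origin + (c(ix, iy) - 0.5) * resolution.

.raster_centers <- function(raster) {
  g <- if (!is.null(raster$presence)) raster$presence else raster$values
  list(x = raster$origin[1] + (seq_len(nrow(g)) - 0.5) * raster$resolution,
       y = raster$origin[2] + (seq_len(ncol(g)) - 0.5) * raster$resolution)
}

#' Rasterise polygons onto a presence grid
#'
#' Burns a list of polygons into a boolean grid over `window` at the given
#' resolution (default 50 m, the scale at which green and blue cover are
#' represented).  A cell is marked present if and only if its centre lies
#' inside any polygon (centre-in-polygon rule).
#'
#' @param polygons List of two-column vertex matrices (metres, open rings).
#' @param window Numeric `c(xmin, ymin, xmax, ymax)` covering the study area.
#' @param resolution Cell size in metres (> 0).
#' @param domain Label for the layer, e.g. `"green"` or `"blue"`.
#' @return An object of class `hli_raster`: list with `domain`, `origin`
#'   (lower-left corner), `resolution` and the logical `presence` matrix.
#' @export
rasterize_features <- function(polygons, window, resolution = 50,
                               domain = "green") {
  window <- as.numeric(window)
  if (length(window) != 4 || window[3] <= window[1] || window[4] <= window[2])
    stop("window must be c(xmin, ymin, xmax, ymax) with positive area",
         call. = FALSE)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  nx <- max(1L, as.integer(ceiling((window[3] - window[1]) / resolution)))
  ny <- max(1L, as.integer(ceiling((window[4] - window[2]) / resolution)))
  pres <- matrix(FALSE, nx, ny)
  xs <- window[1] + (seq_len(nx) - 0.5) * resolution
  ys <- window[2] + (seq_len(ny) - 0.5) * resolution
  for (poly in polygons) {
    bb <- .polygon_bbox(poly)
    ixr <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
    iyr <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(ixr) || !length(iyr)) next
    gx <- rep(xs[ixr], times = length(iyr))
    gy <- rep(ys[iyr], each = length(ixr))
    inside <- .points_in_polygon(gx, gy, poly)
    if (any(inside)) {
      sub <- pres[ixr, iyr, drop = FALSE]
      sub[matrix(inside, length(ixr), length(iyr))] <- TRUE
      pres[ixr, iyr] <- sub
    }
  }
  structure(list(domain = domain, origin = window[1:2],
                 resolution = resolution, presence = pres),
            class = "hli_raster")
}

#' Euclidean distance transform of a presence raster
#'
#' For every cell, the exact Euclidean distance (metres, between cell
#' centres) to the nearest cell marked present.  Present cells map to 0.
#'
#' @param raster An `hli_raster` with at least one present cell.
#' @return An object of class `hli_distance_grid`: the same georeferencing
#'   with a numeric `values` matrix of distances in metres.
#' @export
distance_transform <- function(raster) {
  if (!inherits(raster, "hli_raster"))
    stop("raster must be an hli_raster", call. = FALSE)
  if (!any(raster$presence))
    stop("raster has no present cells; cannot compute distances", call. = FALSE)
  inv <- 1 - (raster$presence * 1)            # foreground = cells off cover
  d <- EBImage::distmap(inv, metric = "euclidean")
  vals <- matrix(as.numeric(d), nrow(raster$presence), ncol(raster$presence)) *
    raster$resolution
  structure(list(domain = raster$domain, origin = raster$origin,
                 resolution = raster$resolution, values = vals),
            class = "hli_distance_grid")
}

#' Median proximity of an area to green or blue cover
#'
#' The median, over all raster cells whose centres fall inside the area's
#' polygon, of the distance-transform values — the access metric used for
#' the two area-phenomenon domains (green and blue space), in km.  If no
#' cell centre falls inside the polygon (a very small area), the value of
#' the cell containing `centroid` is used instead.
#'
#' @param grid An `hli_distance_grid` covering the polygon.
#' @param polygon Two-column vertex matrix (metres).
#' @param centroid Fallback point `c(x, y)`; must lie inside the grid.
#' @return Median distance in km.
#' @export
median_proximity <- function(grid, polygon, centroid) {
  if (!inherits(grid, "hli_distance_grid"))
    stop("grid must be an hli_distance_grid", call. = FALSE)
  ctr <- .raster_centers(grid)
  res <- grid$resolution
  icx <- as.integer(floor((centroid[1] - grid$origin[1]) / res)) + 1L
  icy <- as.integer(floor((centroid[2] - grid$origin[2]) / res)) + 1L
  if (icx < 1L || icy < 1L || icx > nrow(grid$values) || icy > ncol(grid$values))
    stop("centroid lies outside the distance grid", call. = FALSE)
  bb <- .polygon_bbox(polygon)
  ixr <- which(ctr$x >= bb["xmin"] & ctr$x <= bb["xmax"])
  iyr <- which(ctr$y >= bb["ymin"] & ctr$y <= bb["ymax"])
  vals <- numeric(0)
  if (length(ixr) && length(iyr)) {
    gx <- rep(ctr$x[ixr], times = length(iyr))
    gy <- rep(ctr$y[iyr], each = length(ixr))
    inside <- .points_in_polygon(gx, gy, polygon)
    if (any(inside))
      vals <- grid$values[ixr, iyr, drop = FALSE][
        matrix(inside, length(ixr), length(iyr))]
  }
  if (!length(vals)) vals <- grid$values[icx, icy]
  stats::median(vals) / 1000
}

#' @export
print.hli_raster <- function(x, ...) {
  cat(sprintf("Presence raster '%s': %d x %d cells at %g m, %.1f%% cover\n",
              x$domain, nrow(x$presence), ncol(x$presence), x$resolution,
              100 * mean(x$presence)))
  invisible(x)
}
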