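# Assembly of the meshblock x 10-domain access table.

#' Build the access table for a region
#'
#' Computes, for every meshblock, the distance (km) to each of the ten
#' environmental domains: road-network distance from the population-weighted
#' centroid to the nearest facility for the eight point domains, and median
#' proximity over the meshblock's 50 m cells for green and blue cover
#' (distance transform of the presence raster).
#'
#' @param region An `hli_region` from [generate_region()] or [read_region()].
#' @return An object of class `hli_access` (a data frame): `meshblock_id`,
#'   one distance column per domain in the order of [hli_domains()], and a
#'   `prov_<domain>` provenance column per domain (`"network"`,
#'   `"euclidean_fallback"` or `"raster_median"`).  All values are finite
#'   and non-negative.
#' @examples
#' region <- generate_region(generator_config(n_meshblocks = 30, seed = 1))
#' acc <- build_access_table(region)
#' head(acc[, 1:6])
#' @export
build_access_table <- function(region) {
  if (!inherits(region, "hli_region"))
    stop("region must be an hli_region", call. = FALSE)
  for (d in .POINT_DOMAINS)
    if (is.null(region$facilities[[d]]) ||
        nrow(region$facilities[[d]]$points) == 0L)
      stop(sprintf("facility domain '%s' is missing or empty", d),
           call. = FALSE)
  for (d in .RASTER_DOMAINS)
    if (is.null(region$rasters[[d]]))
      stop(sprintf("raster domain '%s' is missing", d), call. = FALSE)

  mb <- region$meshblocks
  n <- nrow(mb)
  origins <- cbind(mb$centroid_x, mb$centroid_y)
  et <- .edge_table(region$network)
  node_ids <- as.character(region$network$nodes$id)
  osnap <- .snap_many(origins, et)

  out <- data.frame(meshblock_id = mb$id, stringsAsFactors = FALSE)
  prov <- list()
  for (d in .DOMAINS) {
    if (d %in% .POINT_DOMAINS) {
      pts <- region$facilities[[d]]$points
      fsnap <- .snap_many(pts, et)
      r <- tryCatch(
        .domain_distances(osnap, origins, fsnap, pts, et, node_ids),
        error = function(e) stop(sprintf("domain '%s': %s", d,
                                         conditionMessage(e)), call. = FALSE))
      out[[d]] <- r$km
      prov[[d]] <- r$provenance
    } else {
      grid <- distance_transform(region$rasters[[d]])
      v <- numeric(n)
      for (i in seq_len(n)) {
        v[i] <- tryCatch(
          median_proximity(grid, region$polygons[[mb$id[i]]],
                           c(mb$centroid_x[i], mb$centroid_y[i])),
          error = function(e) stop(sprintf("meshblock '%s', domain '%s': %s",
                                           mb$id[i], d, conditionMessage(e)),
                                   call. = FALSE))
      }
      out[[d]] <- v
      prov[[d]] <- rep("raster_median", n)
    }
  }
  for (d in .DOMAINS) out[[paste0("prov_", d)]] <- prov[[d]]
  stopifnot(all(vapply(out[.DOMAINS], function(v) all(is.finite(v) & v >= 0),
                       TRUE)))
  class(out) <- c("hli_access", "data.frame")
  out
}

#' @export
print.hli_access <- function(x, ...) {
  cat(sprintf("Access table: %d meshblocks x %d domains (km)\n",
              nrow(x), length(.DOMAINS)))
  fb <- sum(as.matrix(x[paste0("prov_", .POINT_DOMAINS)]) ==
              "euclidean_fallback")
  if (fb > 0) cat(sprintf("  %d cell(s) used the straight-line fallback\n", fb))
  print.data.frame(utils::head(x[, c("meshblock_id", .DOMAINS)], 6),
                   digits = 3)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
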