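# File formats and the end-to-end pipeline.
#
# Open text formats throughout: vector layers as GeoJSON, rasters as ESRI
# ASCII grid (.asc), tables as CSV with a fixed documented column order, and
# a JSON manifest recording seed, configuration and per-stage row counts.

.region_files <- function() {
  c(meshblocks = "meshblocks.geojson",
    setNames(sprintf("facilities_%s.geojson", .POINT_DOMAINS),
             .POINT_DOMAINS),
    network_nodes = "network_nodes.geojson",
    network_edges = "network_edges.csv",
    green = "raster_green.asc", blue = "raster_blue.asc",
    region = "region.json")
}

.write_geojson <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
}

.polygon_feature <- function(poly, props) {
  ring <- lapply(seq_len(nrow(poly) + 1L), function(i) {
    j <- if (i > nrow(poly)) 1L else i
    c(poly[j, 1], poly[j, 2])
  })
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(ring)),
       properties = props)
}

.point_feature <- function(xy, props) {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = c(xy[1], xy[2])),
       properties = props)
}

.write_asc <- function(raster, path) {
  pr <- raster$presence
  nx <- nrow(pr); ny <- ncol(pr)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$resolution),
           "NODATA_value -9999")
  rows <- vapply(rev(seq_len(ny)), function(iy)
    paste(as.integer(pr[, iy]), collapse = " "), "")
  writeLines(c(hdr, rows), path)
}

.read_asc <- function(path, domain) {
  ln <- readLines(path)
  hv <- function(i) as.numeric(strsplit(ln[i], "\\s+")[[1]][2])
  nx <- as.integer(hv(1)); ny <- as.integer(hv(2))
  origin <- c(hv(3), hv(4)); res <- hv(5)
  pr <- matrix(FALSE, nx, ny)
  for (r in seq_len(ny)) {
    vals <- as.integer(strsplit(trimws(ln[6 + r]), "\\s+")[[1]])
    pr[, ny - r + 1L] <- vals != 0L
  }
  structure(list(domain = domain, origin = origin, resolution = res,
                 presence = pr), class = "hli_raster")
}

#' Write a region to a directory of open-format files
#'
#' Meshblocks and network nodes as GeoJSON, facility layers as one GeoJSON
#' point layer per domain (with `polarity`), green/blue presence rasters as
#' ESRI ASCII grids, the edge list as CSV, and the generator configuration
#' as `region.json`.
#'
#' @param region An `hli_region`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_region()]
#' @export
write_region <- function(region, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- .region_files()
  mb <- region$meshblocks
  feats <- lapply(seq_len(nrow(mb)), function(i)
    .polygon_feature(region$polygons[[mb$id[i]]], list(
      id = mb$id[i], population = mb$population[i],
      dep_decile = mb$dep_decile[i], urban_rural = mb$urban_rural[i],
      centroid_x = mb$centroid_x[i], centroid_y = mb$centroid_y[i])))
  .write_geojson(feats, file.path(dir, f[["meshblocks"]]))
  for (d in .POINT_DOMAINS) {
    lay <- region$facilities[[d]]
    feats <- lapply(seq_len(nrow(lay$points)), function(i)
      .point_feature(lay$points[i, ], list(domain = d,
                                           polarity = lay$polarity)))
    .write_geojson(feats, file.path(dir, f[[d]]))
  }
  nodes <- region$network$nodes
  feats <- lapply(seq_len(nrow(nodes)), function(i)
    .point_feature(c(nodes$x[i], nodes$y[i]), list(id = nodes$id[i])))
  .write_geojson(feats, file.path(dir, f[["network_nodes"]]))
  ed <- region$network$edges
  im <- match(ed$from, nodes$id); jm <- match(ed$to, nodes$id)
  utils::write.csv(
    data.frame(from = ed$from, to = ed$to,
               from_x = nodes$x[im], from_y = nodes$y[im],
               to_x = nodes$x[jm], to_y = nodes$y[jm],
               length_m = ed$length_m),
    file.path(dir, f[["network_edges"]]), row.names = FALSE)
  .write_asc(region$rasters$green, file.path(dir, f[["green"]]))
  .write_asc(region$rasters$blue, file.path(dir, f[["blue"]]))
  jsonlite::write_json(
    list(config = unclass(region$config), seed = region$seed,
         window = as.list(region$window)),
    file.path(dir, f[["region"]]), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# All-violations validation; returns a character vector of problems.
.validate_region <- function(region) {
  probs <- character(0)
  add <- function(...) probs <<- c(probs, sprintf(...))
  mb <- region$meshblocks
  bad <- which(!(mb$dep_decile %in% 1:10))
  if (length(bad))
    add("dep_decile outside 1..10 for: %s", paste(mb$id[bad], collapse = ", "))
  bad <- which(mb$population < 0)
  if (length(bad))
    add("negative population for: %s", paste(mb$id[bad], collapse = ", "))
  for (i in seq_len(nrow(mb))) {
    poly <- region$polygons[[mb$id[i]]]
    if (is.null(poly) || nrow(poly) < 3L || abs(.polygon_area(poly)) == 0) {
      add("empty or degenerate polygon for: %s", mb$id[i])
    } else if (!.point_in_polygon(c(mb$centroid_x[i], mb$centroid_y[i]), poly)) {
      add("centroid outside polygon for: %s", mb$id[i])
    }
  }
  miss <- setdiff(.POINT_DOMAINS, names(region$facilities))
  if (length(miss)) add("missing facility domains: %s",
                        paste(miss, collapse = ", "))
  for (d in intersect(.POINT_DOMAINS, names(region$facilities))) {
    lay <- region$facilities[[d]]
    want <- if (d %in% .GOODS) "good" else "bad"
    if (!identical(lay$polarity, want))
      add("facility domain '%s' has polarity '%s', expected '%s'",
          d, lay$polarity, want)
    if (nrow(lay$points) == 0L) add("facility domain '%s' is empty", d)
  }
  for (d in .RASTER_DOMAINS) {
    r <- region$rasters[[d]]
    if (is.null(r)) { add("missing raster domain '%s'", d); next }
    if (!any(r$presence)) add("raster '%s' has no present cells", d)
    if (!is.finite(r$resolution) || r$resolution <= 0)
      add("raster '%s' has invalid resolution", d)
  }
  nodes <- region$network$nodes; edges <- region$network$edges
  unk <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(unk)) add("edges reference unknown nodes: %s",
                       paste(unk, collapse = ", "))
  bad <- which(!is.finite(edges$length_m) | edges$length_m <= 0)
  if (length(bad)) add("non-positive edge lengths at rows: %s",
                       paste(bad, collapse = ", "))
  probs
}

#' Read a region from a directory
#'
#' Loads the layout written by [write_region()] and validates every type
#' invariant on load; validation failures enumerate all violations, not
#' just the first.
#'
#' @param dir Directory containing the region files.
#' @return An `hli_region`.
#' @export
read_region <- function(dir) {
  f <- .region_files()
  missing <- f[!file.exists(file.path(dir, f))]
  if (length(missing))
    stop("missing region layer(s): ",
         paste(names(missing), collapse = ", "), call. = FALSE)
  gj <- function(p) jsonlite::fromJSON(file.path(dir, p),
                                       simplifyVector = FALSE)
  mbj <- gj(f[["meshblocks"]])$features
  mb <- do.call(rbind, lapply(mbj, function(ft) {
    pr <- ft$properties
    data.frame(id = pr$id, population = as.integer(pr$population),
               centroid_x = as.numeric(pr$centroid_x),
               centroid_y = as.numeric(pr$centroid_y),
               dep_decile = as.integer(pr$dep_decile),
               urban_rural = pr$urban_rural, stringsAsFactors = FALSE)
  }))
  polys <- lapply(mbj, function(ft) {
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m[-nrow(m), , drop = FALSE]            # drop closing vertex
  })
  names(polys) <- mb$id
  facilities <- lapply(.POINT_DOMAINS, function(d) {
    fj <- gj(f[[d]])$features
    pts <- do.call(rbind, lapply(fj, function(ft)
      c(ft$geometry$coordinates[[1]], ft$geometry$coordinates[[2]])))
    colnames(pts) <- c("x", "y")
    list(domain = d, polarity = fj[[1]]$properties$polarity, points = pts)
  })
  names(facilities) <- .POINT_DOMAINS
  nj <- gj(f[["network_nodes"]])$features
  nodes <- do.call(rbind, lapply(nj, function(ft)
    data.frame(id = ft$properties$id,
               x = as.numeric(ft$geometry$coordinates[[1]]),
               y = as.numeric(ft$geometry$coordinates[[2]]),
               stringsAsFactors = FALSE)))
  ec <- utils::read.csv(file.path(dir, f[["network_edges"]]),
                        stringsAsFactors = FALSE)
  rj <- jsonlite::fromJSON(file.path(dir, f[["region"]]))
  region <- structure(list(
    meshblocks = mb, polygons = polys,
    network = list(nodes = nodes,
                   edges = data.frame(from = as.character(ec$from),
                                      to = as.character(ec$to),
                                      length_m = ec$length_m,
                                      stringsAsFactors = FALSE)),
    facilities = facilities,
    rasters = list(green = .read_asc(file.path(dir, f[["green"]]), "green"),
                   blue = .read_asc(file.path(dir, f[["blue"]]), "blue")),
    window = unlist(rj$window),
    config = do.call(generator_config, rj$config),
    seed = as.integer(rj$seed)), class = "hli_region")
  probs <- .validate_region(region)
  if (length(probs))
    stop("region validation failed:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  region
}

#' Pipeline configuration
#'
#' @param out_dir Directory for all artifacts.
#' @param generator A [generator_config()]; ignored when `region_dir` is
#'   given.
#' @param region_dir Optional directory with an existing region to load
#'   instead of simulating.
#' @param domains Domain table; must contain exactly 5 goods and 5 bads
#'   (default [hli_domains()]).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `hli_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, generator = generator_config(),
                            region_dir = NULL, domains = hli_domains(),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  ng <- sum(domains$polarity == "good"); nb <- sum(domains$polarity == "bad")
  if (ng != 5L || nb != 5L)
    .stop_config("domains",
                 sprintf("must contain exactly 5 goods and 5 bads (got %d/%d)",
                         ng, nb))
  if (!inherits(generator, "hli_generator_config"))
    generator <- do.call(generator_config, as.list(generator))
  structure(list(out_dir = out_dir, generator = generator,
                 region_dir = region_dir, domains = domains,
                 log_level = log_level),
            class = "hli_pipeline_config")
}

# Order-dependent checksum of a string; identifies a configuration in the
# manifest so artifacts can be matched to the run that produced them.
.config_checksum <- function(s) {
  by <- as.integer(charToRaw(s))
  sprintf("%08x", sum(by * (seq_along(by) %% 997 + 1)) %% 4294967291)
}

#' Run the full pipeline
#'
#' Simulate (or load) a region, compute the access table, the nine-class
#' index and the socio-spatial summaries, writing every artifact under
#' `config$out_dir`: the region layout, `access.csv`, `hli.csv`,
#' `gradient.csv` + `gradient_tests.csv`, `shares*.csv`, `correlation.csv`
#' and `manifest.json` (seed, configuration checksum, per-stage row counts).
#' Rerunning with an identical configuration reproduces identical files.
#'
#' @param config An [pipeline_config()] object.
#' @return The [hli()] object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "hli_pipeline_config"))
    stop("config must be an hli_pipeline_config", call. = FALSE)
  log <- function(stage, fmt, ...) {
    if (config$log_level != "quiet")
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path)) unlink(manifest_path)  # mark rerun as stale

  region <- stage("simulate", {
    r <- if (!is.null(config$region_dir)) read_region(config$region_dir)
         else generate_region(config$generator)
    write_region(r, file.path(out, "region"))
    r
  })
  log("simulate", "%d meshblocks, seed %d", nrow(region$meshblocks),
      region$seed)

  access <- stage("access", {
    a <- build_access_table(region)
    utils::write.csv(a, file.path(out, "access.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    a
  })
  nfb <- sum(as.matrix(access[paste0("prov_", .POINT_DOMAINS)]) ==
               "euclidean_fallback")
  log("access", "%d rows, %d euclidean_fallback cell(s)", nrow(access), nfb)

  index <- stage("index", {
    ix <- hli(access, meshblocks = region$meshblocks)
    utils::write.csv(as.data.frame(ix), file.path(out, "hli.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    ix
  })
  log("index", "%d rows, %d distinct classes", index$n,
      length(unique(index$records$label)))

  sm <- stage("summarise", {
    s <- summary(index)
    med <- cbind(data.frame(group = rownames(s$gradient$medians)),
                 s$gradient$medians)
    utils::write.csv(med, file.path(out, "gradient.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
    utils::write.csv(
      data.frame(domain = names(s$gradient$statistic),
                 statistic = as.numeric(s$gradient$statistic),
                 p_value = as.numeric(s$gradient$p_value)),
      file.path(out, "gradient_tests.csv"), row.names = FALSE,
      fileEncoding = "UTF-8")
    utils::write.csv(s$shares, file.path(out, "shares.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(s$shares_by_quintile,
                     file.path(out, "shares_by_quintile.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(s$shares_by_urban_rural,
                     file.path(out, "shares_by_urban_rural.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(s$correlation, file.path(out, "correlation.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    s
  })
  log("summarise", "overall goods-bads rho = %.3f", sm$correlation$rho[1])

  cfg_json <- as.character(jsonlite::toJSON(
    list(generator = unclass(config$generator),
         domains = config$domains), auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(list(
    seed = region$seed,
    config = list(generator = unclass(config$generator)),
    config_checksum = .config_checksum(cfg_json),
    stages = list(simulate = nrow(region$meshblocks),
                  access = nrow(access), index = index$n,
                  summarise = nrow(sm$shares)),
    euclidean_fallback_cells = nfb,
    status = "complete"),
    manifest_path, auto_unbox = TRUE, digits = NA)
  log("pipeline", "complete; artifacts in %s", out)
  invisible(index)
}
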