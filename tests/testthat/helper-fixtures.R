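# Shared fixtures, built in code and cached for the session.

.fx <- new.env(parent = emptyenv())

fixture_region <- function(n = 60, g = 0.8, seed = 1) {
  key <- sprintf("r_%d_%s_%d", n, g, seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_region(
      generator_config(n_meshblocks = n, gradient_strength = g, seed = seed))
  .fx[[key]]
}

fixture_access <- function(n = 60, g = 0.8, seed = 1) {
  key <- sprintf("a_%d_%s_%d", n, g, seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_access_table(fixture_region(n, g, seed))
  .fx[[key]]
}

# A-B-C straight line, 1000 m edges along the x axis.
line_network <- function() {
  list(nodes = data.frame(id = c("A", "B", "C"),
                          x = c(0, 1000, 2000), y = c(0, 0, 0),
                          stringsAsFactors = FALSE),
       edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                          length_m = c(1000, 1000), stringsAsFactors = FALSE))
}

# Random connected network: points uniform in a square, chain along x order
# (guarantees connectivity) plus each node's 2 nearest neighbours.
random_network <- function(n_nodes, seed, extent = 5000) {
  set.seed(seed)
  x <- runif(n_nodes, 0, extent); y <- runif(n_nodes, 0, extent)
  ids <- sprintf("N%03d", seq_len(n_nodes))
  ord <- order(x)
  from <- ids[ord[-n_nodes]]; to <- ids[ord[-1]]
  for (i in seq_len(n_nodes)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2); d[i] <- Inf
    for (j in order(d)[1:2]) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b))
  ix <- match(a[keep], ids); jx <- match(b[keep], ids)
  len <- sqrt((x[ix] - x[jx])^2 + (y[ix] - y[jx])^2)
  list(nodes = data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE),
       edges = data.frame(from = a[keep], to = b[keep], length_m = len,
                          stringsAsFactors = FALSE))
}

# Random 10-domain access table with unique continuous distances.
random_access <- function(n, seed) {
  set.seed(seed)
  doms <- hli_domains()$domain
  out <- data.frame(meshblock_id = sprintf("MB%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (d in doms) out[[d]] <- round(runif(n, 0.01, 8), 6)
  out
}

# Hand-built 5-meshblock region: unit 1 km square cells in a row along a
# straight road, one facility per point domain, small green patch and a
# blue strip along the top edge.
hand_region <- function() {
  cs <- 1000
  ids <- sprintf("MB%d", 1:5)
  polys <- lapply(0:4, function(k)
    cbind(c(k, k + 1, k + 1, k) * cs, c(0, 0, 1, 1) * cs))
  names(polys) <- ids
  mb <- data.frame(id = ids, population = c(80L, 90L, 100L, 70L, 110L),
                   centroid_x = (0:4) * cs + 500, centroid_y = 500,
                   dep_decile = c(1L, 3L, 5L, 8L, 10L),
                   urban_rural = c("major_urban", "large_urban", "medium_urban",
                                   "small_urban", "rural_other"),
                   stringsAsFactors = FALSE)
  network <- list(
    nodes = data.frame(id = ids, x = mb$centroid_x, y = mb$centroid_y,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = ids[1:4], to = ids[2:5], length_m = cs,
                       stringsAsFactors = FALSE))
  doms <- c("physical_activity", "supermarket", "fruit_veg", "fast_food",
            "takeaway", "dairy_convenience", "alcohol", "gaming")
  goods <- c("physical_activity", "supermarket", "fruit_veg")
  fx <- c(500, 1500, 2400, 3100, 4500, 700, 2500, 4100)
  fy <- c(500, 700, 500, 300, 500, 500, 900, 500)
  facilities <- lapply(seq_along(doms), function(i)
    list(domain = doms[i],
         polarity = if (doms[i] %in% goods) "good" else "bad",
         points = matrix(c(fx[i], fy[i]), 1, 2,
                         dimnames = list(NULL, c("x", "y")))))
  names(facilities) <- doms
  window <- c(xmin = 0, ymin = 0, xmax = 5000, ymax = 1000)
  green <- rasterize_features(
    list(cbind(c(800, 1400, 1400, 800), c(200, 200, 800, 800))),
    window, 50, domain = "green")
  blue <- rasterize_features(
    list(cbind(c(0, 5000, 5000, 0), c(900, 900, 1000, 1000))),
    window, 50, domain = "blue")
  structure(list(meshblocks = mb, polygons = polys, network = network,
                 facilities = facilities,
                 rasters = list(green = green, blue = blue),
                 window = window,
                 config = generator_config(n_meshblocks = 20, seed = 1),
                 seed = 1L),
            class = "hli_region")
}
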