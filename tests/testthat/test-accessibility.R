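test_that("snapping projects onto the nearest edge with the documented tie rule", {
  net <- line_network()
  # point coincident with node B
  s <- snap_to_network(c(1000, 0), net)
  expect_equal(s$access_offset, 0)
  expect_true((identical(unname(s$edge), c("A", "B")) && s$offset == 1000) ||
              (identical(unname(s$edge), c("B", "C")) && s$offset == 0))
  # 30 m perpendicular from the midpoint of a 1000 m edge
  s <- snap_to_network(c(500, 30), net)
  expect_equal(unname(s$edge), c("A", "B"))
  expect_equal(s$offset, 500)
  expect_equal(s$access_offset, 30)
})

test_that("snapping equals the exhaustive segment-scan oracle on random networks", {
  net <- random_network(50, seed = 7)
  et <- hli:::.edge_table(net)
  set.seed(8)
  pts <- cbind(runif(100, -500, 5500), runif(100, -500, 5500))
  for (i in seq_len(nrow(pts))) {
    s <- hli:::.snap_one(pts[i, 1], pts[i, 2], et)
    o <- ora_snap(pts[i, ], net)
    expect_equal(s$access_offset, o$d, tolerance = 1e-9)
    expect_equal(c(s$x, s$y), unname(o$q), tolerance = 1e-6)
  }
})

test_that("euclidean nearest distance: triangle, identity and naive-scan oracle", {
  expect_equal(euclidean_nearest_distance(c(0, 0), rbind(c(3000, 4000))), 5)
  expect_equal(euclidean_nearest_distance(c(10, 10), rbind(c(10, 10))), 0)
  set.seed(3)
  facs <- cbind(runif(1000, 0, 1e4), runif(1000, 0, 1e4))
  o <- c(5000, 5000)
  naive <- min(sqrt((facs[, 1] - o[1])^2 + (facs[, 2] - o[2])^2)) / 1000
  expect_equal(euclidean_nearest_distance(o, facs), naive)
  expect_error(euclidean_nearest_distance(o, facs[0, , drop = FALSE]), "empty")
})

test_that("network nearest distance: identities and path sums on a line network", {
  net <- line_network()
  expect_equal(as.numeric(network_nearest_distance(c(0, 0), rbind(c(0, 0)), net)), 0)
  expect_equal(as.numeric(network_nearest_distance(c(0, 0), rbind(c(2000, 0)), net)), 2)
  # same-edge case: |offset difference|
  expect_equal(as.numeric(network_nearest_distance(c(200, 0), rbind(c(900, 0)), net)),
               0.7)
  # off-network origin: access leg included
  expect_equal(as.numeric(network_nearest_distance(c(500, 40), rbind(c(2000, 0)), net)),
               (40 + 1500) / 1000)
  expect_error(network_nearest_distance(c(0, 0), matrix(0, 0, 2), net), "empty")
})

test_that("network nearest distance equals the brute-force split-edge Dijkstra oracle", {
  for (seed in 1:5) {
    net <- random_network(80, seed = seed)
    set.seed(seed + 100)
    origins <- cbind(runif(4, 0, 5000), runif(4, 0, 5000))
    facs <- cbind(runif(3, 0, 5000), runif(3, 0, 5000))
    for (i in seq_len(nrow(origins))) {
      got <- as.numeric(network_nearest_distance(origins[i, ], facs, net))
      want <- ora_network_nearest(origins[i, ], facs, net)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("network distance respects the euclidean lower bound and facility monotonicity", {
  net <- random_network(60, seed = 21)
  set.seed(22)
  origins <- cbind(runif(25, 0, 5000), runif(25, 0, 5000))
  facs <- cbind(runif(8, 0, 5000), runif(8, 0, 5000))
  for (i in seq_len(nrow(origins))) {
    for (k in seq_len(nrow(facs))) {
      nd <- as.numeric(network_nearest_distance(origins[i, ],
                                                facs[k, , drop = FALSE], net))
      ed <- euclidean_nearest_distance(origins[i, ], facs[k, , drop = FALSE])
      expect_gte(nd, ed - 1e-6)
    }
    # adding facilities never increases the distance
    d3 <- as.numeric(network_nearest_distance(origins[i, ], facs[1:3, ], net))
    d8 <- as.numeric(network_nearest_distance(origins[i, ], facs, net))
    expect_lte(d8, d3 + 1e-12)
  }
})

test_that("unreachable facilities fall back to euclidean distance with a flag", {
  net <- list(
    nodes = data.frame(id = c("A", "B", "C", "D"),
                       x = c(0, 1000, 5000, 6000), y = 0,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = c("A", "C"), to = c("B", "D"),
                       length_m = c(1000, 1000), stringsAsFactors = FALSE))
  expect_warning(
    d <- network_nearest_distance(c(0, 0), rbind(c(6000, 0)), net),
    "fallback")
  expect_equal(as.numeric(d), 6)
  expect_identical(attr(d, "provenance"), "euclidean_fallback")
})

test_that("rasterisation follows the centre-in-polygon rule", {
  win <- c(0, 0, 200, 200)
  full <- rasterize_features(list(cbind(c(-1, 201, 201, -1),
                                        c(-1, -1, 201, 201))), win, 50)
  expect_true(all(full$presence))
  expect_identical(dim(full$presence), c(4L, 4L))
  # axis-aligned 100 x 100 square at the origin covers exactly 2 x 2 centres
  sq <- rasterize_features(list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))),
                           win, 50)
  expect_identical(sum(sq$presence), 4L)
  expect_true(all(sq$presence[1:2, 1:2]))
  # polygon squeezed between two columns of centres hits nothing
  thin <- rasterize_features(list(cbind(c(30, 40, 40, 30), c(0, 0, 200, 200))),
                             win, 50)
  expect_false(any(thin$presence))
  expect_error(distance_transform(thin), "no present cells")
  expect_error(rasterize_features(list(), c(0, 0, 0, 100), 50), "positive area")
})

test_that("distance transform is exact euclidean, symmetric, and matches brute force", {
  win <- c(0, 0, 350, 350)
  r <- rasterize_features(list(cbind(c(150, 200, 200, 150),
                                     c(150, 150, 200, 200))), win, 50)
  expect_identical(sum(r$presence), 1L)   # lone centre at cell (4, 4)
  dg <- distance_transform(r)
  expect_equal(dg$values[4, 4], 0)
  expect_equal(dg$values[4, 5], 50)
  expect_equal(dg$values[5, 5], 50 * sqrt(2), tolerance = 1e-9)

  set.seed(13)
  pr <- matrix(runif(15 * 12) < 0.12, 15, 12)
  if (!any(pr)) pr[7, 5] <- TRUE
  rr <- structure(list(domain = "green", origin = c(0, 0), resolution = 50,
                       presence = pr), class = "hli_raster")
  expect_equal(distance_transform(rr)$values, ora_edt(pr, 50), tolerance = 1e-9)
  # reflecting the presence grid reflects the distances
  rf <- rr; rf$presence <- pr[nrow(pr):1, ]
  expect_equal(distance_transform(rf)$values,
               distance_transform(rr)$values[nrow(pr):1, ], tolerance = 1e-9)
})

test_that("median proximity takes the median over interior cell centres, with centroid fallback", {
  mkgrid <- function(vals) structure(
    list(domain = "green", origin = c(0, 0), resolution = 50, values = vals),
    class = "hli_distance_grid")
  # all-zero cover: 0 km
  g0 <- mkgrid(matrix(0, 6, 6))
  poly <- cbind(c(0, 300, 300, 0), c(0, 0, 300, 300))
  expect_equal(median_proximity(g0, poly, c(150, 150)), 0)
  # three covered cells valued 0 / 50 / 100 m -> median 0.05 km
  v <- matrix(1e6, 6, 6); v[1, 1] <- 0; v[2, 1] <- 50; v[3, 1] <- 100
  strip <- cbind(c(0, 150, 150, 0), c(0, 0, 50, 50))
  expect_equal(median_proximity(mkgrid(v), strip, c(75, 25)), 0.05)
  # tiny polygon with no interior centres: value of the centroid's cell
  v2 <- matrix(0, 6, 6); v2[4, 4] <- 200
  tiny <- cbind(c(160, 162, 162, 160), c(160, 160, 162, 162)) + 10
  expect_equal(median_proximity(mkgrid(v2), tiny, c(171, 171)), 0.2)
  expect_error(median_proximity(mkgrid(v2), tiny, c(1e5, 1e5)), "outside")
})

test_that("access table has the documented shape and provenance", {
  a <- fixture_access(60, 0.8, 1)
  doms <- hli_domains()$domain
  expect_identical(nrow(a), 60L)
  expect_true(all(doms %in% names(a)))
  for (d in doms) expect_true(all(is.finite(a[[d]]) & a[[d]] >= 0))
  for (d in doms[hli_domains()$type == "point"])
    expect_true(all(a[[paste0("prov_", d)]] %in%
                    c("network", "euclidean_fallback")))
  for (d in c("green", "blue"))
    expect_true(all(a[[paste0("prov_", d)]] == "raster_median"))
})

test_that("a supermarket at a meshblock centroid yields a zero cell", {
  r <- fixture_region(60, 0.8, 1)
  r$facilities$supermarket$points[3, ] <-
    c(r$meshblocks$centroid_x[5], r$meshblocks$centroid_y[5])
  a <- build_access_table(r)
  expect_equal(a$supermarket[5], 0)
})

test_that("hand-built 5-meshblock region matches per-cell oracles", {
  r <- hand_region()
  a <- build_access_table(r)
  for (d in names(r$facilities)) {
    for (i in 1:5) {
      want <- ora_network_nearest(
        c(r$meshblocks$centroid_x[i], r$meshblocks$centroid_y[i]),
        r$facilities[[d]]$points, r$network)
      expect_equal(a[[d]][i], want, tolerance = 1e-9,
                   label = sprintf("%s/MB%d", d, i))
    }
  }
  for (d in c("green", "blue")) {
    dt <- ora_edt(r$rasters[[d]]$presence, 50)
    ctr <- hli:::.raster_centers(r$rasters[[d]])
    for (i in 1:5) {
      poly <- r$polygons[[i]]
      gx <- rep(ctr$x, times = length(ctr$y))
      gy <- rep(ctr$y, each = length(ctr$x))
      inside <- hli:::.points_in_polygon(gx, gy, poly)
      want <- median(dt[matrix(inside, length(ctr$x), length(ctr$y))]) / 1000
      expect_equal(a[[d]][i], want, tolerance = 1e-9,
                   label = sprintf("%s/MB%d", d, i))
    }
  }
})
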