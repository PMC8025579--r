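# Synthetic study region generator.
#
# Emulates a small-area census geography: meshblock-like units of 60-120
# residents tiling a rectangular window, a connected road network, eight
# point-facility domains, green/blue cover rasters, an area-deprivation
# decile with spatial structure, and a plantable association between
# deprivation and facility provision ("bads" denser in deprived areas).

# Share of deprivation-score variance carried by meshblock-level noise rather
# than the smooth spatial field.  Real deprivation indices are spatially
# autocorrelated but show strong block-to-block variation; the nugget keeps
# deciles from forming solid spatial clusters, so that under a zero planted
# gradient the deciles behave exchangeably with respect to facility access.
.DEP_NUGGET <- 0.1

# Acceptance-probability strength multipliers per point domain: the planted
# gradient applies fully to the five bads and mildly to supermarkets and
# physical-activity facilities (some goods are also closer in deprived areas).
.GRADIENT_STRENGTH_MULT <- c(
  physical_activity = 0.4, supermarket = 0.4, fruit_veg = 0,
  fast_food = 1, takeaway = 1, dairy_convenience = 1, alcohol = 1, gaming = 1
)

#' Configuration for the synthetic region generator
#'
#' @param n_meshblocks Number of small-area units (>= 20).
#' @param urban_fraction Fraction of meshblocks assigned to the four urban
#'   classes, in `[0, 1]`.
#' @param gradient_strength Planted deprivation-accessibility association in
#'   `[-1, 1]`.  Positive values place health-constraining facilities
#'   preferentially in deprived areas (and, mildly, supermarkets and
#'   physical-activity facilities); 0 makes facility placement independent
#'   of deprivation; negative values reverse the gradient.
#' @param facilities_per_domain Facilities per point domain (>= 1).  The
#'   default scales with region size (1.2 facilities per meshblock,
#'   minimum 5): a dense, urban-like provisioning in which the
#'   nearest-facility distance is determined at the meshblock scale.
#' @param cell_size Nominal meshblock width in metres (lattice pitch).
#' @param resolution Raster cell size in metres for green/blue cover
#'   (default 50).
#' @param seed Integer seed; together with the other fields it fully
#'   determines the region.
#' @return An object of class `hli_generator_config`.
#' @seealso [generate_region()]
#' @export
generator_config <- function(n_meshblocks = 500L, urban_fraction = 0.6,
                             gradient_strength = 0.8,
                             facilities_per_domain = NULL,
                             cell_size = 300, resolution = 50, seed = 1L) {
  n <- as.integer(n_meshblocks)
  if (is.na(n) || n < 20L)
    .stop_config("n_meshblocks", "must be an integer >= 20")
  if (is.null(facilities_per_domain))
    facilities_per_domain <- max(5L, as.integer(round(1.2 * n)))
  if (!is.finite(urban_fraction) || urban_fraction < 0 || urban_fraction > 1)
    .stop_config("urban_fraction", "must lie in [0, 1]")
  if (!is.finite(gradient_strength) ||
      gradient_strength < -1 || gradient_strength > 1)
    .stop_config("gradient_strength", "must lie in [-1, 1]")
  m <- as.integer(facilities_per_domain)
  if (is.na(m) || m < 1L)
    .stop_config("facilities_per_domain", "must be an integer >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    .stop_config("cell_size", "must be > 0")
  if (!is.finite(resolution) || resolution <= 0)
    .stop_config("resolution", "must be > 0")
  seed <- as.integer(seed)
  if (is.na(seed)) .stop_config("seed", "must be an integer")
  structure(
    list(n_meshblocks = n, urban_fraction = as.numeric(urban_fraction),
         gradient_strength = as.numeric(gradient_strength),
         facilities_per_domain = m,
         cell_size = as.numeric(cell_size),
         resolution = as.numeric(resolution), seed = seed),
    class = "hli_generator_config"
  )
}

# Regular 24-gon approximating a circle; adequate at 50 m raster resolution.
.circle_poly <- function(cx, cy, r, k = 24L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Sum of Gaussian bumps evaluated at (x, y).
.bump_field <- function(x, y, bumps) {
  v <- numeric(length(x))
  for (b in seq_len(nrow(bumps))) {
    d2 <- (x - bumps[b, "cx"])^2 + (y - bumps[b, "cy"])^2
    v <- v + bumps[b, "amp"] * exp(-d2 / (2 * bumps[b, "sd"]^2))
  }
  v
}

#' Generate a synthetic study region
#'
#' Produces a complete, self-contained region: convex quadrilateral
#' meshblocks on a jittered lattice, per-meshblock population (60-120) and
#' population-weighted centroid from simulated dwellings, a spatially
#' structured deprivation decile, an urban/rural class, a connected road
#' network over meshblock centroids, eight point-facility layers whose
#' placement intensity scales with local deprivation (balanced allocation,
#' road-frontage positions), and 50 m green/blue presence rasters (blue
#' includes window-boundary coastline cells).
#'
#' The result is a pure function of the configuration: the same
#' `hli_generator_config` always reproduces a bit-identical region.  Each
#' layer draws from its own named random substream, so adding facilities to
#' one domain never perturbs another layer.
#'
#' @param config An [generator_config()] object.
#' @return An object of class `hli_region`: a list with elements
#'   `meshblocks` (data frame: `id`, `population`, `centroid_x`,
#'   `centroid_y`, `dep_decile`, `urban_rural`), `polygons` (named list of
#'   two-column vertex matrices), `network` (list of `nodes` and `edges`
#'   data frames), `facilities` (named list of eight point layers),
#'   `rasters` (green and blue `hli_raster`), `window`, `config`, `seed`.
#' @examples
#' region <- generate_region(generator_config(n_meshblocks = 30, seed = 1))
#' region
#' @export
generate_region <- function(config) {
  if (!inherits(config, "hli_generator_config"))
    config <- do.call(generator_config, as.list(config))
  n  <- config$n_meshblocks
  cs <- config$cell_size
  g  <- config$gradient_strength
  seed <- config$seed

  ncolg <- max(2L, floor(sqrt(n)))
  nrowg <- as.integer(ceiling(n / ncolg))
  W <- ncolg * cs; H <- nrowg * cs
  window <- c(xmin = 0, ymin = 0, xmax = W, ymax = H)

  ## -- geometry: jittered shared lattice vertices (convex quads) ----------
  polys <- .with_seed(.substream(seed, 1), {
    jx <- matrix(runif((ncolg + 1) * (nrowg + 1), -0.2, 0.2) * cs,
                 ncolg + 1, nrowg + 1)
    jy <- matrix(runif((ncolg + 1) * (nrowg + 1), -0.2, 0.2) * cs,
                 ncolg + 1, nrowg + 1)
    jx[c(1, ncolg + 1), ] <- 0   # keep the window rectangular
    jy[, c(1, nrowg + 1)] <- 0
    vx <- outer(0:ncolg, rep(1, nrowg + 1)) * cs + jx
    vy <- outer(rep(1, ncolg + 1), 0:nrowg) * cs + jy
    lapply(seq_len(n), function(k) {
      ix <- (k - 1L) %% ncolg + 1L
      iy <- (k - 1L) %/% ncolg + 1L
      cbind(c(vx[ix, iy], vx[ix + 1, iy], vx[ix + 1, iy + 1], vx[ix, iy + 1]),
            c(vy[ix, iy], vy[ix + 1, iy], vy[ix + 1, iy + 1], vy[ix, iy + 1]))
    })
  })
  ids <- sprintf("MB%0*d", nchar(as.character(n)), seq_len(n))
  names(polys) <- ids

  ## -- dwellings: population and population-weighted centroid -------------
  dw <- .with_seed(.substream(seed, 2), {
    population <- sample(60:120, n, replace = TRUE)
    cent <- matrix(0, n, 2)
    for (k in seq_len(n)) {
      nd <- max(1L, as.integer(round(population[k] / 2)))  # ~2 residents/dwelling
      pts <- .sample_in_polygon(nd, polys[[k]])
      w <- as.vector(rmultinom(1, population[k], rep(1, nd)))
      cent[k, ] <- population_weighted_centroid(pts, w)
    }
    list(population = population, centroid = cent)
  })
  cx <- dw$centroid[, 1]; cy <- dw$centroid[, 2]

  ## -- deprivation: smooth bump field + meshblock nugget ------------------
  dep <- .with_seed(.substream(seed, 3), {
    K <- 6L
    # bump centres drawn in an expanded window (edge correction) so the
    # field is stationary over the study area rather than systematically
    # mid-range along the window boundary
    bumps <- cbind(cx = runif(K, -0.25 * W, 1.25 * W),
                   cy = runif(K, -0.25 * H, 1.25 * H),
                   sd = runif(K, 0.10, 0.22) * max(W, H),
                   amp = runif(K, 0.5, 1.5) * sample(c(-1, 1), K, replace = TRUE))
    smooth <- .bump_field(cx, cy, bumps)
    z <- (smooth - mean(smooth)) / max(stats::sd(smooth), 1e-12)
    score <- sqrt(1 - .DEP_NUGGET) * z + sqrt(.DEP_NUGGET) * rnorm(n)
    list(bumps = bumps, smooth = smooth, score = score)
  })
  dep_decile <- as.integer(ceiling(10 * rank(dep$score, ties.method = "first") / n))

  ## -- urban/rural classes: settlement-intensity quantiles ----------------
  urban_rural <- .with_seed(.substream(seed, 4), {
    K <- 4L
    ub <- cbind(cx = runif(K, -0.25 * W, 1.25 * W),
                cy = runif(K, -0.25 * H, 1.25 * H),
                sd = runif(K, 0.08, 0.18) * max(W, H),
                amp = runif(K, 0.8, 1.5))
    sett <- .bump_field(cx, cy, ub) + rnorm(n, sd = 1e-6)  # tie breaking
    q <- rank(sett, ties.method = "first") / n
    uf <- config$urban_fraction
    cls <- character(n)
    urb <- q > 1 - uf
    if (any(urb)) {
      u <- (q[urb] - (1 - uf)) / max(uf, 1e-12)
      cls[urb] <- as.character(cut(u, c(-Inf, 0.25, 0.5, 0.75, Inf),
                                   labels = c("small_urban", "medium_urban",
                                              "large_urban", "major_urban")))
    }
    if (any(!urb)) {
      r <- q[!urb] / max(1 - uf, 1e-12)
      cls[!urb] <- ifelse(r > 0.8, "rural_settlement", "rural_other")
    }
    cls
  })

  ## -- road network: lattice-adjacent centroids, plus some diagonals ------
  network <- .with_seed(.substream(seed, 5), {
    from <- integer(0); to <- integer(0)
    for (k in seq_len(n)) {
      ix <- (k - 1L) %% ncolg + 1L
      if (ix < ncolg && k + 1L <= n) { from <- c(from, k); to <- c(to, k + 1L) }
      if (k + ncolg <= n)            { from <- c(from, k); to <- c(to, k + ncolg) }
    }
    diag_ok <- ((from - 1L) %% ncolg + 1L) < ncolg & (to == from + ncolg) &
      (from + ncolg + 1L) <= n
    cand <- from[diag_ok][runif(sum(diag_ok)) < 0.25]
    from <- c(from, cand); to <- c(to, cand + ncolg + 1L)
    len <- sqrt((cx[from] - cx[to])^2 + (cy[from] - cy[to])^2)
    list(nodes = data.frame(id = ids, x = cx, y = cy,
                            stringsAsFactors = FALSE),
         edges = data.frame(from = ids[from], to = ids[to], length_m = len,
                            stringsAsFactors = FALSE))
  })

  ## -- facilities: balanced allocation against local deprivation ----------
  # Local deprivation of a meshblock is its deprivation-score quantile,
  # spread uniformly over [0, 1].  Facility intensity scales geometrically
  # with it (ratio ~37 between the most and least deprived areas at full
  # strength), so expected nearest-facility distance is graded between
  # every pair of adjacent deprivation deciles.  Each meshblock receives
  # floor(mu) facilities plus one more with probability frac(mu) — a
  # balanced (variance-reduced) form of intensity-proportional placement —
  # uniformly within its polygon and projected onto the nearest road edge
  # (premises face streets).
  score_q <- rank(dep$score, ties.method = "first") / n
  m <- config$facilities_per_domain
  fac_et <- .edge_table(network)
  facilities <- lapply(seq_along(.POINT_DOMAINS), function(d) {
    dom <- .POINT_DOMAINS[d]
    st <- .GRADIENT_STRENGTH_MULT[[dom]] * abs(g)
    s_dir <- if (g >= 0) score_q else 1 - score_q
    w <- exp(4.5 * st * (s_dir - 1))
    mu <- m * w / sum(w)
    pts <- .with_seed(.substream(seed, 10 + d), {
      extra <- runif(n) < (mu - floor(mu))
      counts <- as.integer(floor(mu)) + extra
      if (sum(counts) == 0L) counts[which.max(mu)] <- 1L
      out <- matrix(numeric(0), ncol = 2)
      for (k in which(counts > 0L))
        out <- rbind(out, .sample_in_polygon(counts[k], polys[[k]]))
      out
    })
    # snap onto road frontage
    sn <- .snap_many(pts, fac_et)
    pts <- cbind(sn$x, sn$y)
    colnames(pts) <- c("x", "y")
    list(domain = dom,
         polarity = if (dom %in% .GOODS) "good" else "bad",
         points = pts)
  })
  names(facilities) <- .POINT_DOMAINS

  ## -- green/blue presence rasters ----------------------------------------
  rasters <- .with_seed(.substream(seed, 6), {
    npatch <- max(5L, as.integer(round(n / 30)))
    gpoly <- lapply(seq_len(npatch), function(i)
      .circle_poly(runif(1, 0, W), runif(1, 0, H), runif(1, 200, 600)))
    green <- rasterize_features(gpoly, window, config$resolution, domain = "green")
    lpoly <- lapply(1:3, function(i)
      .circle_poly(runif(1, 0, W), runif(1, 0, H), runif(1, 150, 400)))
    blue <- rasterize_features(lpoly, window, config$resolution, domain = "blue")
    # coastline: the window boundary is water
    pr <- blue$presence
    pr[1, ] <- TRUE; pr[nrow(pr), ] <- TRUE
    pr[, 1] <- TRUE; pr[, ncol(pr)] <- TRUE
    blue$presence <- pr
    list(green = green, blue = blue)
  })

  structure(
    list(
      meshblocks = data.frame(
        id = ids, population = dw$population,
        centroid_x = cx, centroid_y = cy,
        dep_decile = dep_decile, urban_rural = urban_rural,
        stringsAsFactors = FALSE),
      polygons = polys,
      network = network,
      facilities = facilities,
      rasters = rasters,
      window = window,
      config = config,
      seed = seed
    ),
    class = "hli_region"
  )
}

#' @export
print.hli_region <- function(x, ...) {
  mb <- x$meshblocks
  cat("Synthetic study region\n")
  cat(sprintf("  meshblocks: %d (population %d-%d, total %d)\n",
              nrow(mb), min(mb$population), max(mb$population),
              sum(mb$population)))
  cat(sprintf("  window: %.1f x %.1f km\n",
              (x$window["xmax"] - x$window["xmin"]) / 1000,
              (x$window["ymax"] - x$window["ymin"]) / 1000))
  cat(sprintf("  road network: %d nodes, %d edges\n",
              nrow(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  facilities: %d domains x %d points\n",
              length(x$facilities), nrow(x$facilities[[1]]$points)))
  cat(sprintf("  gradient_strength: %.2f, seed: %d\n",
              x$config$gradient_strength, x$seed))
  invisible(x)
}

#' @export
print.hli_generator_config <- function(x, ...) {
  cat("Synthetic region generator configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
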