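# Road-network distances: snapping points onto edges, splitting edges at
# snap offsets, and shortest paths (igraph Dijkstra) from area centroids to
# the nearest facility of a domain.
#
# Reported distances always include both access legs (straight-line metres
# from the original point to its snap point), which keeps the
# facility-at-centroid identity exact and prevents zero-cost teleportation
# onto the network.

# Canonical edge table: endpoints ordered lexicographically, with endpoint
# coordinates attached.  Orientation (and hence `offset`) is always measured
# from the lexicographically smaller node id.
.edge_table <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  if (is.null(nodes) || is.null(edges) || nrow(edges) == 0L)
    stop("network is empty", call. = FALSE)
  from <- as.character(edges$from); to <- as.character(edges$to)
  miss <- setdiff(unique(c(from, to)), as.character(nodes$id))
  if (length(miss))
    stop("edges reference unknown nodes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(edges$length_m) | edges$length_m <= 0))
    stop("edge lengths must be positive and finite", call. = FALSE)
  swap <- from > to
  a <- ifelse(swap, to, from); b <- ifelse(swap, from, to)
  ix <- match(a, nodes$id); jx <- match(b, nodes$id)
  data.frame(a = a, b = b, length_m = edges$length_m,
             ax = nodes$x[ix], ay = nodes$y[ix],
             bx = nodes$x[jx], by = nodes$y[jx],
             stringsAsFactors = FALSE)
}

# Snap one point onto the canonical edge table.  Ties (equal snap distance)
# are broken by the lexicographically smallest (a, b) node-id pair.
.snap_one <- function(px, py, et) {
  pr <- .project_on_segment(px, py, et$ax, et$ay, et$bx, et$by)
  dmin <- min(pr$dist)
  cand <- which(pr$dist <= dmin + 1e-9)
  cand <- cand[order(et$a[cand], et$b[cand])]
  e <- cand[1]
  list(edge_idx = e, t = pr$t[e], offset = pr$t[e] * et$length_m[e],
       access_offset = pr$dist[e], x = pr$x[e], y = pr$y[e])
}

.snap_many <- function(pts, et) {
  n <- nrow(pts)
  out <- data.frame(edge_idx = integer(n), offset = numeric(n),
                    access_offset = numeric(n), x = numeric(n), y = numeric(n))
  dx <- et$bx - et$ax; dy <- et$by - et$ay
  len2 <- pmax(dx * dx + dy * dy, 1e-300)
  block <- max(1L, as.integer(2e6 / nrow(et)))
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    px <- pts[lo:hi, 1]; py <- pts[lo:hi, 2]
    # blocked point x edge projection (rows = points)
    t <- (outer(px, dx) - rep(et$ax * dx, each = length(px)) +
          outer(py, dy) - rep(et$ay * dy, each = length(px))) /
      rep(len2, each = length(px))
    t <- pmin(pmax(t, 0), 1)
    qx <- rep(et$ax, each = length(px)) + t * rep(dx, each = length(px))
    qy <- rep(et$ay, each = length(px)) + t * rep(dy, each = length(px))
    d2 <- (px - qx)^2 + (py - qy)^2
    for (i in seq_along(px)) {
      di <- sqrt(d2[i, ])
      dmin <- min(di)
      cand <- which(di <= dmin + 1e-9)
      cand <- cand[order(et$a[cand], et$b[cand])]
      e <- cand[1]
      j <- lo + i - 1L
      out$edge_idx[j] <- e
      out$offset[j] <- t[i, e] * et$length_m[e]
      out$access_offset[j] <- di[e]
      out$x[j] <- qx[i, e]; out$y[j] <- qy[i, e]
    }
  }
  out
}

#' Snap a point to the nearest position on a road network
#'
#' Finds the nearest point on any network edge by perpendicular projection
#' clamped to the edge endpoints.  Ties are broken by the smallest
#' (node-id pair) in lexicographic order; the edge is reported with its
#' endpoints in that canonical order and `offset` measured from the first.
#'
#' @param point Numeric `c(x, y)` in metres.
#' @param network List with `nodes` (`id`, `x`, `y`) and `edges`
#'   (`from`, `to`, `length_m`) data frames.
#' @return An object of class `hli_network_location`: list with `edge`
#'   (`c(from, to)`), `offset` (metres along the edge), `access_offset`
#'   (straight-line metres from `point` to the snap position) and `snap`
#'   (coordinates of the snap position).
#' @export
snap_to_network <- function(point, network) {
  et <- .edge_table(network)
  s <- .snap_one(point[1], point[2], et)
  structure(list(edge = c(from = et$a[s$edge_idx], to = et$b[s$edge_idx]),
                 offset = s$offset, access_offset = s$access_offset,
                 snap = c(x = s$x, y = s$y)),
            class = "hli_network_location")
}

#' Straight-line distance to the nearest facility
#'
#' @param origin Numeric `c(x, y)` in metres.
#' @param facilities Two-column matrix of facility coordinates (metres).
#' @return Minimum Euclidean distance in km.
#' @export
euclidean_nearest_distance <- function(origin, facilities) {
  facilities <- rbind(facilities)
  if (nrow(facilities) == 0L)
    stop("facility list is empty", call. = FALSE)
  min(sqrt((facilities[, 1] - origin[1])^2 +
           (facilities[, 2] - origin[2])^2)) / 1000
}

# Build the augmented graph with facility snap nodes inserted (edges split
# at their offsets) and return, for every original node, the minimum of
# [facility access offset + shortest path from the facility's snap node].
.facility_node_field <- function(et, fsnap, node_ids) {
  k <- nrow(fsnap)
  fnames <- sprintf("..fac%d", seq_len(k))
  keep <- !(seq_len(nrow(et)) %in% fsnap$edge_idx)
  ef <- character(0); etn <- character(0); ew <- numeric(0)
  for (e in unique(fsnap$edge_idx)) {
    on_e <- which(fsnap$edge_idx == e)
    on_e <- on_e[order(fsnap$offset[on_e])]
    chain <- c(et$a[e], fnames[on_e], et$b[e])
    offs <- c(0, fsnap$offset[on_e], et$length_m[e])
    ef <- c(ef, chain[-length(chain)])
    etn <- c(etn, chain[-1])
    ew <- c(ew, pmax(diff(offs), 0))
  }
  edges_aug <- data.frame(
    from = c(et$a[keep], ef),
    to = c(et$b[keep], etn),
    weight = c(et$length_m[keep], ew),
    stringsAsFactors = FALSE)
  verts <- data.frame(name = c(node_ids, fnames), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges_aug, directed = FALSE,
                                     vertices = verts)
  dm <- igraph::distances(g, v = fnames, to = node_ids,
                          weights = igraph::E(g)$weight)
  dm <- dm + fsnap$access_offset          # recycled down rows (one per facility)
  apply(dm, 2, min)
}

# Distances (km) from many snapped origins to the nearest of many snapped
# facilities, with euclidean fallback when no facility is reachable.
.domain_distances <- function(osnap, origins, fsnap, fac_pts, et, node_ids) {
  D <- .facility_node_field(et, fsnap, node_ids)
  ua <- match(et$a[osnap$edge_idx], node_ids)
  ub <- match(et$b[osnap$edge_idx], node_ids)
  len <- et$length_m[osnap$edge_idx]
  best <- pmin(osnap$access_offset + osnap$offset + D[ua],
               osnap$access_offset + (len - osnap$offset) + D[ub])
  # facilities snapped onto the origin's own edge: direct along-edge term
  for (e in intersect(unique(osnap$edge_idx), unique(fsnap$edge_idx))) {
    oi <- which(osnap$edge_idx == e)
    fi <- which(fsnap$edge_idx == e)
    for (i in oi) {
      direct <- osnap$access_offset[i] +
        abs(osnap$offset[i] - fsnap$offset[fi]) + fsnap$access_offset[fi]
      best[i] <- min(best[i], direct)
    }
  }
  # a facility exactly coincident with an origin is at distance zero by
  # definition (no access legs to walk)
  for (i in seq_along(best)) {
    if (min((fac_pts[, 1] - origins[i, 1])^2 +
            (fac_pts[, 2] - origins[i, 2])^2) <= 1e-12) best[i] <- 0
  }
  prov <- rep("network", length(best))
  bad <- !is.finite(best)
  if (any(bad)) {
    for (i in which(bad))
      best[i] <- 1000 * euclidean_nearest_distance(origins[i, ], fac_pts)
    prov[bad] <- "euclidean_fallback"
    warning(sprintf(
      "%d origin(s) cannot reach any facility on the network; %s",
      sum(bad), "straight-line fallback distances used"), call. = FALSE)
  }
  list(km = best / 1000, provenance = prov)
}

#' Road-network distance to the nearest facility
#'
#' Snaps the origin and every facility onto the network, splits edges at
#' the snap offsets, and returns the minimum over facilities of
#' [origin access leg + shortest path along the network + facility access
#' leg], in km.  If the origin and a facility snap to the same edge the
#' along-edge distance `|offset difference|` is also considered.  When no
#' facility is reachable (disconnected network), the straight-line distance
#' is returned instead with a warning; the provenance attribute then reads
#' `"euclidean_fallback"`.
#'
#' @param origin Numeric `c(x, y)` in metres.
#' @param facilities Two-column matrix of facility coordinates (metres).
#' @param network List with `nodes` and `edges` data frames.
#' @return Distance in km with attribute `provenance` (`"network"` or
#'   `"euclidean_fallback"`).
#' @examples
#' net <- list(nodes = data.frame(id = c("A", "B", "C"),
#'                                x = c(0, 1000, 2000), y = 0),
#'             edges = data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                length_m = c(1000, 1000)))
#' network_nearest_distance(c(0, 0), rbind(c(2000, 0)), net)  # 2 km
#' @export
network_nearest_distance <- function(origin, facilities, network) {
  facilities <- rbind(facilities)
  if (nrow(facilities) == 0L)
    stop("facility list is empty", call. = FALSE)
  et <- .edge_table(network)
  node_ids <- as.character(network$nodes$id)
  osnap <- .snap_many(rbind(origin), et)
  fsnap <- .snap_many(facilities, et)
  r <- .domain_distances(osnap, rbind(origin), fsnap, facilities, et, node_ids)
  structure(r$km, provenance = r$provenance)
}
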