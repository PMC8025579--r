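# Independent naive implementations used as oracles.  Everything here is
# deliberately brute force (exhaustive scans, O(V^2) Dijkstra, O(n^2) ranks)
# and shares no code with the package internals.

# -- plain Dijkstra over an edge-list network (O(V^2) scan) ----------------
ora_dijkstra <- function(nodes, edges, source) {
  ids <- nodes$id
  nv <- length(ids)
  ef <- match(c(edges$from, edges$to), ids)
  et <- match(c(edges$to, edges$from), ids)
  ew <- c(edges$length_m, edges$length_m)
  adj_to <- split(et, ef)
  adj_w <- split(ew, ef)
  dist <- rep(Inf, nv)
  dist[match(source, ids)] <- 0
  done <- rep(FALSE, nv)
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    nb <- adj_to[[as.character(u)]]
    if (!is.null(nb)) {
      alt <- dist[u] + adj_w[[as.character(u)]]
      ag <- tapply(alt, nb, min)            # parallel-edge safe
      idx <- as.integer(names(ag))
      imp <- ag < dist[idx]
      dist[idx[imp]] <- ag[imp]
    }
  }
  setNames(dist, ids)
}

# Exhaustive snap of a point onto the nearest network segment.
ora_snap <- function(p, network) {
  nd <- network$nodes; ed <- network$edges
  best <- NULL
  for (e in seq_len(nrow(ed))) {
    a <- c(nd$x[nd$id == ed$from[e]], nd$y[nd$id == ed$from[e]])
    b <- c(nd$x[nd$id == ed$to[e]], nd$y[nd$id == ed$to[e]])
    ab2 <- sum((b - a)^2)
    t <- if (ab2 > 0) sum((p - a) * (b - a)) / ab2 else 0
    t <- min(max(t, 0), 1)
    q <- a + t * (b - a)
    d <- sqrt(sum((p - q)^2))
    if (is.null(best) || d < best$d - 1e-9) best <- list(e = e, t = t, d = d, q = q)
  }
  best
}

# Brute-force nearest-facility network distance with edge splitting: every
# point (origin and facilities) is snapped exhaustively, all snap nodes are
# inserted into the edge list, and a hand Dijkstra runs from the origin.
ora_network_nearest <- function(origin, facilities, network, fsnaps = NULL) {
  facilities <- rbind(facilities)
  nd <- network$nodes; ed <- network$edges
  if (is.null(fsnaps))
    fsnaps <- lapply(seq_len(nrow(facilities)), function(i)
      ora_snap(facilities[i, ], network))
  snaps <- c(list(ora_snap(origin, network)), fsnaps)
  # group snap points by host edge, split each edge at the sorted offsets
  pnames <- c("..p0", sprintf("..p%d", seq_len(nrow(facilities))))
  newnodes <- data.frame(
    id = c(nd$id, pnames),
    x = c(nd$x, vapply(snaps, function(s) s$q[1], 0)),
    y = c(nd$y, vapply(snaps, function(s) s$q[2], 0)),
    stringsAsFactors = FALSE)
  host <- vapply(snaps, function(s) s$e, 0L)
  fv <- character(0); tv <- character(0); wv <- numeric(0)
  for (e in seq_len(nrow(ed))) {
    on_e <- which(host == e)
    if (!length(on_e)) {
      fv <- c(fv, ed$from[e]); tv <- c(tv, ed$to[e])
      wv <- c(wv, ed$length_m[e])
    } else {
      on_e <- on_e[order(vapply(snaps[on_e], function(s) s$t, 0))]
      chain <- c(ed$from[e], pnames[on_e], ed$to[e])
      offs <- c(0, vapply(snaps[on_e], function(s) s$t, 0) * ed$length_m[e],
                ed$length_m[e])
      fv <- c(fv, chain[-length(chain)]); tv <- c(tv, chain[-1])
      wv <- c(wv, pmax(diff(offs), 0))
    }
  }
  newedges <- data.frame(from = fv, to = tv, length_m = wv,
                         stringsAsFactors = FALSE)
  dist <- ora_dijkstra(newnodes, newedges, "..p0")
  total <- snaps[[1]]$d +
    vapply(seq_len(nrow(facilities)), function(k)
      dist[pnames[k + 1]] + snaps[[k + 1]]$d, 0)
  direct0 <- sqrt((facilities[, 1] - origin[1])^2 +
                  (facilities[, 2] - origin[2])^2)
  if (any(direct0 <= 1e-9)) return(0)
  min(total) / 1000
}

# Brute-force Euclidean distance transform, metres.
ora_edt <- function(presence, resolution) {
  nx <- nrow(presence); ny <- ncol(presence)
  tr <- which(presence, arr.ind = TRUE)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    out[i, j] <- sqrt(min((tr[, 1] - i)^2 + (tr[, 2] - j)^2)) * resolution
  }
  out
}

# O(n^2) ordinal ranks, ties by ascending id.
ora_rank <- function(d, ids) {
  ids <- as.character(ids)
  vapply(seq_along(d), function(i)
    1L + sum(d < d[i] | (d == d[i] & ids < ids[i])), 1L)
}

# Naive full index pipeline on an access table (data frame with
# meshblock_id and the ten domain columns).
ora_hli <- function(access) {
  doms <- c("green", "blue", "physical_activity", "supermarket", "fruit_veg",
            "fast_food", "takeaway", "dairy_convenience", "alcohol", "gaming")
  goods <- doms[1:5]; bads <- doms[6:10]
  ids <- as.character(access$meshblock_id)
  n <- nrow(access)
  rk <- sapply(doms, function(d) ora_rank(access[[d]], ids))
  gsum <- rowSums(rk[, goods, drop = FALSE])
  bsum <- rowSums(rk[, bads, drop = FALSE])
  grank <- ora_rank(gsum, ids); brank <- ora_rank(bsum, ids)
  gdec <- as.integer(ceiling(10 * grank / n))
  bdec <- as.integer(ceiling(10 * brank / n))
  cat3 <- function(dec) ifelse(dec <= 3, 1L, ifelse(dec <= 7, 2L, 3L))
  gc3 <- cat3(gdec); bc3 <- cat3(bdec)
  data.frame(meshblock_id = ids, stringsAsFactors = FALSE,
             goods_rank_sum = as.integer(gsum), bads_rank_sum = as.integer(bsum),
             goods_rank = grank, bads_rank = brank,
             goods_decile = gdec, bads_decile = bdec,
             goods_category = gc3, bads_category = bc3,
             label = paste0(gc3, "–", bc3))
}

# Pooled mean Spearman correlation between deprivation decile and
# straight-line nearest-bad distance over the five bad domains.
ora_pooled_bad_spearman <- function(region) {
  mb <- region$meshblocks
  bads <- c("fast_food", "takeaway", "dairy_convenience", "alcohol", "gaming")
  mean(vapply(bads, function(d) {
    pts <- region$facilities[[d]]$points
    dd <- vapply(seq_len(nrow(mb)), function(i)
      min(sqrt((pts[, 1] - mb$centroid_x[i])^2 +
               (pts[, 2] - mb$centroid_y[i])^2)), 0)
    cor(mb$dep_decile, dd, method = "spearman")
  }, 0))
}
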