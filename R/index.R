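# The healthy location index: per-domain ordinal ranks, goods/bads composite
# ranks, deciles, 3-level access categories, and the combined 9-class label.
#
# Everything here depends on distances only through their within-domain
# ordering, and no domain carries a weight.

# The nine labels in healthiness order: goods category crossed with bads
# category, en-dash separated.  "1-3" (best goods access, worst bads access)
# is healthiest; "3-1" unhealthiest; mixed classes are ordered symmetrically
# by (goods category) - (bads category), ties by goods category ascending.
.HLI_LABEL_ORDER <- c("1–3", "1–2", "2–3", "1–1",
                      "2–2", "3–3", "2–1", "3–2",
                      "3–1")

#' The nine index labels in healthiness order
#'
#' @return Character vector of the nine `goods–bads` labels ordered from the
#'   healthiest class (`"1–3"`, best access to goods, worst access to bads)
#'   to the unhealthiest (`"3–1"`).  Positions give the healthiness rank
#'   1..9.  The two extremes are fixed by the construction of the index; the
#'   ordering of the mixed classes is a package convention used for sorting
#'   and plotting.
#' @export
hli_labels <- function() .HLI_LABEL_ORDER

#' Rank meshblocks within one domain
#'
#' Ordinal ranks 1..N ascending by distance, 1 being the closest to the
#' feature.  Ties are broken by ascending meshblock id, so each domain's
#' ranks are always an exact permutation of 1..N.
#'
#' @param distances Finite numeric vector of distances (km).
#' @param ids Meshblock ids, same length; used only for tie breaking.
#' @return Integer vector of ranks aligned with the input.
#' @examples
#' rank_domain(c(0.5, 0.2, 0.9), c("a", "b", "c"))  # 2 1 3
#' @export
rank_domain <- function(distances, ids = seq_along(distances)) {
  if (length(distances) != length(ids))
    stop("distances and ids must have equal length", call. = FALSE)
  bad <- !is.finite(distances)
  if (any(bad))
    stop("non-finite distances for ids: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  n <- length(distances)
  r <- integer(n)
  r[order(distances, as.character(ids))] <- seq_len(n)
  r
}

#' Composite rank over one polarity side
#'
#' Sums the five per-domain ranks of one side (goods or bads) and ranks the
#' sums again with the same tie rule, yielding the combined-access rank.
#' Domains are unweighted: the sum is invariant to their order.
#'
#' @param rank_table Data frame of per-domain integer rank columns.
#' @param side `"goods"` or `"bads"`, selecting the five domains of that
#'   polarity; alternatively supply `domains` explicitly (testing mode with
#'   other domain counts).
#' @param ids Meshblock ids for tie breaking (default row order).
#' @param domains Optional explicit character vector of column names,
#'   overriding `side`.
#' @return List with `rank_sum` (integer) and `rank` (permutation of 1..N).
#' @export
composite_rank <- function(rank_table, side = c("goods", "bads"),
                           ids = seq_len(nrow(rank_table)), domains = NULL) {
  if (is.null(domains)) {
    side <- match.arg(side)
    domains <- if (side == "goods") .GOODS else .BADS
    if (!all(domains %in% names(rank_table)))
      .stop_config("domains", sprintf(
        "rank table must contain the 5 %s columns (%s)", side,
        paste(setdiff(domains, names(rank_table)), collapse = ", ")))
  } else if (!all(domains %in% names(rank_table))) {
    .stop_config("domains", "not all named columns are present")
  }
  sums <- as.integer(rowSums(rank_table[, domains, drop = FALSE]))
  list(rank_sum = sums, rank = rank_domain(sums, ids))
}

#' Assign equal-count deciles to ranks
#'
#' `decile(r) = ceiling(10 r / N)` for ranks 1..N: decile 1 holds the
#' best-access meshblocks, decile 10 the worst, and decile sizes differ by
#' at most one.
#'
#' @param ranks Integer vector forming a permutation of 1..N, N >= 10.
#' @return Integer deciles in 1..10.
#' @export
assign_deciles <- function(ranks) {
  n <- length(ranks)
  if (n < 10L)
    stop("deciles are undefined for fewer than 10 meshblocks", call. = FALSE)
  if (!setequal(ranks, seq_len(n)))
    stop("ranks must be a permutation of 1..N", call. = FALSE)
  as.integer(ceiling(10 * as.numeric(ranks) / n))
}

#' Collapse deciles into three access categories
#'
#' Category 1 is the best accessibility (deciles 1-3), category 2 mid
#' accessibility (deciles 4-7), category 3 the worst (deciles 8-10).
#'
#' @param decile Integer vector with values in 1..10.
#' @return Integer categories in 1..3.
#' @export
collapse_categories <- function(decile) {
  if (any(!decile %in% 1:10))
    stop("deciles must lie in 1..10", call. = FALSE)
  c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L)[decile]
}

#' Combine goods and bads categories into the nine-class label
#'
#' @param goods_category,bads_category Integer vectors in 1..3.
#' @return Data frame with `goods_category`, `bads_category`, `label`
#'   (`"goods–bads"`, en-dash) and `healthiness_rank` (1 = healthiest
#'   `"1–3"`, 9 = unhealthiest `"3–1"`; see [hli_labels()]).
#' @examples
#' combine_hli(1, 3)  # healthiest class
#' @export
combine_hli <- function(goods_category, bads_category) {
  if (any(!goods_category %in% 1:3) || any(!bads_category %in% 1:3))
    stop("categories must lie in 1..3", call. = FALSE)
  label <- paste0(goods_category, "–", bads_category)
  data.frame(goods_category = as.integer(goods_category),
             bads_category = as.integer(bads_category),
             label = label,
             healthiness_rank = match(label, .HLI_LABEL_ORDER),
             stringsAsFactors = FALSE)
}

#' Compute the healthy location index from an access table
#'
#' Runs the full deterministic pipeline: per-domain ordinal ranks, goods and
#' bads rank sums, composite ranks, deciles (`ceiling(10 r / N)`), 3-level
#' categories (1-3 / 4-7 / 8-10) and the combined nine-class label.  All
#' domains are unweighted and all stages depend on distances only through
#' their within-domain ordering.
#'
#' @param access An `hli_access` table (or any data frame with a
#'   `meshblock_id` column and the ten domain distance columns).
#' @return An object of class `hli`; see [hli()] for its structure and
#'   methods.
#' @export
compute_hli <- function(access) {
  if (!all(.DOMAINS %in% names(access)))
    stop("access table must contain the 10 domain columns: ",
         paste(setdiff(.DOMAINS, names(access)), collapse = ", "),
         call. = FALSE)
  ids <- if ("meshblock_id" %in% names(access))
    as.character(access$meshblock_id) else as.character(seq_len(nrow(access)))
  if (anyDuplicated(ids))
    stop("meshblock ids must be unique", call. = FALSE)
  n <- nrow(access)
  ranks <- data.frame(meshblock_id = ids, stringsAsFactors = FALSE)
  for (d in .DOMAINS) ranks[[d]] <- rank_domain(access[[d]], ids)
  cg <- composite_rank(ranks, "goods", ids)
  cb <- composite_rank(ranks, "bads", ids)
  goods_decile <- assign_deciles(cg$rank)
  bads_decile <- assign_deciles(cb$rank)
  composite <- data.frame(
    meshblock_id = ids,
    goods_rank_sum = cg$rank_sum, bads_rank_sum = cb$rank_sum,
    goods_rank = cg$rank, bads_rank = cb$rank,
    goods_decile = goods_decile, bads_decile = bads_decile,
    stringsAsFactors = FALSE)
  rec <- combine_hli(collapse_categories(goods_decile),
                     collapse_categories(bads_decile))
  records <- cbind(data.frame(meshblock_id = ids, stringsAsFactors = FALSE),
                   rec)
  structure(list(access = access, ranks = ranks, composite = composite,
                 records = records, n = n, meshblocks = NULL),
            class = "hli")
}

#' Healthy location index of a region
#'
#' The central entry point: computes the ten-domain access table (for a
#' region) and the full nine-class index.  The returned object carries the
#' distances, per-domain ranks, composite scores and the per-meshblock
#' index record, and has `print`, `summary`, `plot` and `as.data.frame`
#' methods.
#'
#' @param x An `hli_region` (access table computed via
#'   [build_access_table()]) or an access table data frame.
#' @param ... Unused.
#' @return An object of class `hli`: list with `access`, `ranks`,
#'   `composite`, `records` data frames (one row per meshblock), `n`, and
#'   `meshblocks` (area attributes, when a region was supplied).
#' @examples
#' region <- generate_region(generator_config(n_meshblocks = 40, seed = 1))
#' ix <- hli(region)
#' ix
#' table(ix$records$label)
#' @export
hli <- function(x, ...) UseMethod("hli")

#' @rdname hli
#' @export
hli.hli_region <- function(x, ...) {
  res <- compute_hli(build_access_table(x))
  res$meshblocks <- x$meshblocks
  res
}

#' @rdname hli
#' @export
hli.data.frame <- function(x, meshblocks = NULL, ...) {
  res <- compute_hli(x)
  res$meshblocks <- meshblocks
  res
}

#' @export
print.hli <- function(x, ...) {
  cat(sprintf("Healthy location index: %d meshblocks\n", x$n))
  tab <- table(factor(x$records$label, levels = .HLI_LABEL_ORDER))
  cat("Class counts (healthiest to unhealthiest):\n")
  print(tab)
  invisible(x)
}

#' Full per-meshblock output table of an index
#'
#' @param x An `hli` object.
#' @param ... Unused.
#' @return Data frame with meshblock id, the 10 distance columns, the 10
#'   rank columns (`rank_<domain>`), goods/bads rank sums, composite ranks,
#'   deciles, categories and the combined label — the layout written by the
#'   pipeline's `hli.csv`.
#' @export
as.data.frame.hli <- function(x, ...) {
  out <- data.frame(meshblock_id = x$records$meshblock_id,
                    stringsAsFactors = FALSE)
  for (d in .DOMAINS) out[[d]] <- x$access[[d]]
  for (d in .DOMAINS) out[[paste0("rank_", d)]] <- x$ranks[[d]]
  for (cn in c("goods_rank_sum", "bads_rank_sum", "goods_rank", "bads_rank",
               "goods_decile", "bads_decile"))
    out[[cn]] <- x$composite[[cn]]
  out$goods_category <- x$records$goods_category
  out$bads_category <- x$records$bads_category
  out$hli_label <- x$records$label
  out$healthiness_rank <- x$records$healthiness_rank
  out
}
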