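# Socio-spatial descriptive summaries: median access by deprivation decile
# (with a group-difference test), population shares by index class, and the
# goods-bads rank correlation.

.dep_quintile <- function(decile) as.integer(ceiling(decile / 2))

#' Median distance by deprivation decile
#'
#' Per-domain median distances (km) for the whole region and for each
#' deprivation decile, with a Kruskal-Wallis test for group differences per
#' domain.  Medians are meshblock-weighted (one observation per area unit),
#' not population-weighted.
#'
#' @param access An `hli_access` table (or data frame with `meshblock_id`
#'   and the domain columns).
#' @param meshblocks Data frame with `id` and `dep_decile` for every
#'   meshblock in `access`.
#' @return An object of class `hli_gradient`: list with `medians` (rows
#'   `overall`, `D1`..`D10`; one column per domain), `statistic` and
#'   `p_value` (named per domain).
#' @export
median_distance_by_deprivation <- function(access, meshblocks) {
  dep <- meshblocks$dep_decile[match(access$meshblock_id, meshblocks$id)]
  if (any(is.na(dep)))
    stop("missing dep_decile for meshblocks: ",
         paste(utils::head(access$meshblock_id[is.na(dep)], 5),
               collapse = ", "), call. = FALSE)
  rows <- c("overall", paste0("D", 1:10))
  med <- matrix(NA_real_, length(rows), length(.DOMAINS),
                dimnames = list(rows, .DOMAINS))
  stat <- p <- setNames(numeric(length(.DOMAINS)), .DOMAINS)
  for (d in .DOMAINS) {
    v <- access[[d]]
    med["overall", d] <- stats::median(v)
    for (k in 1:10)
      if (any(dep == k)) med[paste0("D", k), d] <- stats::median(v[dep == k])
    if (length(unique(dep)) < 2L) {
      stat[d] <- NA_real_; p[d] <- NA_real_   # no contrast to test
    } else {
      gt <- group_difference_test(v, dep)
      stat[d] <- gt$statistic; p[d] <- gt$p_value
    }
  }
  structure(list(medians = as.data.frame(med), statistic = stat, p_value = p),
            class = "hli_gradient")
}

#' @export
print.hli_gradient <- function(x, digits = 2, ...) {
  cat("Median distance (km) by deprivation decile\n")
  print(round(x$medians, digits))
  cat("\nGroup differences (Kruskal-Wallis):\n")
  out <- data.frame(H = round(x$statistic, 1),
                    p = format.pval(x$p_value, digits = 2))
  print(out)
  invisible(x)
}

#' Nonparametric test for group differences
#'
#' Kruskal-Wallis rank-sum test (chi-square approximation), matching the
#' rank-based construction of the index and the skewed shape of distance
#' distributions.  Optionally also computes a permutation p-value by
#' shuffling group labels.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; at least two non-empty groups.
#' @param permutations Number of label permutations for an optional
#'   permutation p-value (0 = skip).
#' @param seed Seed for the permutations.
#' @return List with `statistic` (H), `p_value` (chi-square approximation)
#'   and, when requested, `p_value_permutation`.
#' @export
group_difference_test <- function(values, groups, permutations = 0,
                                  seed = 1L) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("at least two non-empty groups are required", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (length(unique(values)) == 1L) {
    res <- list(statistic = 0, p_value = 1)          # no variation at all
    if (permutations > 0) res$p_value_permutation <- 1
    return(res)
  }
  kt <- stats::kruskal.test(values, groups)
  res <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
  if (permutations > 0) {
    obs <- res$statistic
    exc <- .with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(permutations)) {
        ks <- stats::kruskal.test(values, sample(groups))$statistic
        if (ks >= obs - 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
    res$p_value_permutation <- (1 + exc) / (permutations + 1)
  }
  res
}

#' Population share by index class
#'
#' Population-weighted share (%) of each nine-class label, overall or within
#' deprivation quintiles (`ceiling(decile / 2)`) or urban/rural classes.
#' Zero-population meshblocks contribute nothing; a grouping level with no
#' population is dropped with a warning.
#'
#' @param records Per-meshblock index records (the `records` element of an
#'   [hli()] object, or any data frame with `meshblock_id` and `label`).
#' @param meshblocks Data frame with `id`, `population` and (as needed)
#'   `dep_decile` / `urban_rural`.
#' @param by Grouping: `"none"`, `"dep_quintile"` or `"urban_rural"`.
#' @return Data frame of class `hli_shares` with `level`, `label`,
#'   `population` and `share_pct`; shares sum to 100 within each level.
#' @export
population_share_by_hli <- function(records, meshblocks,
                                    by = c("none", "dep_quintile",
                                           "urban_rural")) {
  by <- match.arg(by)
  mi <- match(records$meshblock_id, meshblocks$id)
  if (any(is.na(mi)))
    stop("records contain meshblocks absent from the meshblock table",
         call. = FALSE)
  pop <- meshblocks$population[mi]
  level <- switch(by,
    none = rep("all", nrow(records)),
    dep_quintile = paste0("Q", .dep_quintile(meshblocks$dep_decile[mi])),
    urban_rural = as.character(meshblocks$urban_rural[mi]))
  levs <- sort(unique(level))
  out <- NULL
  for (lv in levs) {
    sel <- level == lv
    tot <- sum(pop[sel])
    if (tot == 0) {
      warning(sprintf("grouping level '%s' has zero population; dropped", lv),
              call. = FALSE)
      next
    }
    ptab <- tapply(pop[sel], factor(records$label[sel],
                                    levels = .HLI_LABEL_ORDER), sum)
    ptab[is.na(ptab)] <- 0
    out <- rbind(out, data.frame(
      level = lv, label = .HLI_LABEL_ORDER,
      population = as.numeric(ptab),
      share_pct = 100 * as.numeric(ptab) / tot,
      stringsAsFactors = FALSE))
  }
  class(out) <- c("hli_shares", "data.frame")
  out
}

#' Correlation between goods and bads composite ranks
#'
#' Spearman rank correlation between the goods and bads composite ranks,
#' overall and (optionally) within deprivation quintiles — the co-occurrence
#' measure of the index: positive values mean areas with good access to
#' health-promoting features also tend to have good access to
#' health-constraining ones.
#'
#' @param composite The `composite` element of an [hli()] object (or a data
#'   frame with `meshblock_id`, `goods_rank`, `bads_rank`).
#' @param meshblocks Data frame with `id` and `dep_decile` (needed for
#'   `by = "dep_quintile"`).
#' @param by `"none"` or `"dep_quintile"`.
#' @return Data frame with `group`, `n` and `rho`; groups of fewer than 3
#'   meshblocks get `NA`.
#' @export
goods_bads_rank_correlation <- function(composite, meshblocks = NULL,
                                        by = c("none", "dep_quintile")) {
  by <- match.arg(by)
  sp <- function(a, b) if (length(a) < 3L) NA_real_ else
    stats::cor(a, b, method = "spearman")
  out <- data.frame(group = "overall", n = nrow(composite),
                    rho = sp(composite$goods_rank, composite$bads_rank),
                    stringsAsFactors = FALSE)
  if (by == "dep_quintile") {
    if (is.null(meshblocks))
      stop("meshblocks with dep_decile required for by = 'dep_quintile'",
           call. = FALSE)
    qu <- .dep_quintile(
      meshblocks$dep_decile[match(composite$meshblock_id, meshblocks$id)])
    for (q in sort(unique(qu))) {
      sel <- qu == q
      out <- rbind(out, data.frame(
        group = paste0("Q", q), n = sum(sel),
        rho = sp(composite$goods_rank[sel], composite$bads_rank[sel]),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Socio-spatial summary of an index
#'
#' @param object An [hli()] object whose `meshblocks` element is set (i.e.
#'   built from a region).
#' @param ... Unused.
#' @return An object of class `summary.hli`: list with `gradient`
#'   (median distance by deprivation decile), `shares` (population share by
#'   class, overall), `shares_by_quintile`, `shares_by_urban_rural` and
#'   `correlation` (goods-bads rank correlation overall and by quintile).
#' @export
summary.hli <- function(object, ...) {
  mb <- object$meshblocks
  if (is.null(mb))
    stop("summary requires an index built from a region (meshblocks unset)",
         call. = FALSE)
  structure(list(
    gradient = median_distance_by_deprivation(object$access, mb),
    shares = population_share_by_hli(object$records, mb, "none"),
    shares_by_quintile = population_share_by_hli(object$records, mb,
                                                 "dep_quintile"),
    shares_by_urban_rural = population_share_by_hli(object$records, mb,
                                                    "urban_rural"),
    correlation = goods_bads_rank_correlation(object$composite, mb,
                                              "dep_quintile"),
    n = object$n), class = "summary.hli")
}

#' @export
print.summary.hli <- function(x, ...) {
  print(x$gradient)
  cat("\nPopulation share (%) by index class:\n")
  sh <- x$shares
  print(data.frame(label = sh$label, share_pct = round(sh$share_pct, 2)))
  cat("\nGoods-bads rank correlation (Spearman):\n")
  print(transform(x$correlation, rho = round(rho, 3)))
  invisible(x)
}

#' Plot method for an index
#'
#' Stacked population shares by class (overall, or grouped by deprivation
#' quintile / urban-rural class) using base graphics.
#'
#' @param x An [hli()] object with `meshblocks` set.
#' @param by `"none"`, `"dep_quintile"` or `"urban_rural"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the share table plotted.
#' @export
plot.hli <- function(x, by = c("none", "dep_quintile", "urban_rural"), ...) {
  by <- match.arg(by)
  if (is.null(x$meshblocks))
    stop("plotting requires an index built from a region", call. = FALSE)
  sh <- population_share_by_hli(x$records, x$meshblocks, by)
  m <- tapply(sh$share_pct, list(factor(sh$label, levels = .HLI_LABEL_ORDER),
                                 sh$level), sum)
  cols <- grDevices::hcl.colors(9, "RdYlBu", rev = TRUE)
  graphics::barplot(m, col = cols, border = NA,
                    ylab = "population share (%)",
                    legend.text = gsub("–", "-", rownames(m)),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(sh)
}
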