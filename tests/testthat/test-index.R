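test_that("domain ranks are ordinal with ties broken by ascending id", {
  expect_identical(rank_domain(c(0.5, 0.2, 0.9), c("a", "b", "c")),
                   c(2L, 1L, 3L))
  expect_identical(rank_domain(c(0.2, 0.2, 0.9), c("a", "b", "c")),
                   c(1L, 2L, 3L))
  expect_error(rank_domain(c(1, NA, 2), c("a", "b", "c")), "b")
  set.seed(5)
  d <- sample(round(runif(200, 0, 3), 1))      # plenty of ties
  ids <- sprintf("M%03d", sample(200))
  expect_identical(rank_domain(d, ids), ora_rank(d, ids))
})

test_that("composite ranks sum five unweighted domains and re-rank with the same tie rule", {
  # degenerate single-domain mode: composite equals the domain rank
  rt <- data.frame(green = c(2L, 1L, 3L))
  cr <- composite_rank(rt, ids = c("a", "b", "c"), domains = "green")
  expect_identical(cr$rank, rt$green)
  # two-domain tie resolved by id
  rt2 <- data.frame(g1 = c(1L, 2L, 3L), g2 = c(2L, 1L, 3L))
  cr2 <- composite_rank(rt2, ids = c("a", "b", "c"), domains = c("g1", "g2"))
  expect_identical(cr2$rank_sum, c(3L, 3L, 6L))
  expect_identical(cr2$rank, c(1L, 2L, 3L))
  # permuting the domain order leaves the sums unchanged (no weights)
  set.seed(9)
  acc <- random_access(50, seed = 9)
  ix <- compute_hli(acc)
  goods <- c("green", "blue", "physical_activity", "supermarket", "fruit_veg")
  for (perm in list(rev(goods), sample(goods))) {
    cr <- composite_rank(ix$ranks, ids = acc$meshblock_id, domains = perm)
    expect_identical(cr$rank_sum, ix$composite$goods_rank_sum)
  }
  # five random domains, 100 meshblocks, vs naive sum-and-sort oracle
  acc <- random_access(100, seed = 10)
  ix <- compute_hli(acc)
  o <- ora_hli(acc)
  expect_identical(ix$composite$goods_rank, o$goods_rank)
  expect_identical(ix$composite$bads_rank, o$bads_rank)
  expect_error(composite_rank(ix$ranks, domains = "nope"), "configuration")
})

test_that("deciles follow ceiling(10 r / N) with equal counts", {
  expect_identical(assign_deciles(1:10), 1:10)
  expect_identical(assign_deciles(1:25)[13], 6L)
  big <- assign_deciles(1:52923)
  expect_identical(big[1], 1L)
  expect_identical(big[52923], 10L)
  for (n in c(10, 25, 500, 52923)) {
    dec <- assign_deciles(sample(n))
    expect_lte(diff(range(table(dec))), 1)
  }
  expect_error(assign_deciles(1:9), "fewer than 10")
  expect_error(assign_deciles(c(1L, 1L, 3:10)), "permutation")
})

test_that("decile-to-category collapse uses the 1-3 / 4-7 / 8-10 cut points", {
  expect_identical(collapse_categories(1:10),
                   c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_error(collapse_categories(11), "1..10")
})

test_that("the nine-class combination anchors 1-3 healthiest and 3-1 unhealthiest", {
  expect_identical(combine_hli(1, 3)$label, "1–3")
  expect_identical(combine_hli(1, 3)$healthiness_rank, 1L)
  expect_identical(combine_hli(3, 1)$healthiness_rank, 9L)
  expect_identical(combine_hli(2, 2)$healthiness_rank, 5L)
  full <- combine_hli(rep(1:3, each = 3), rep(1:3, 3))
  expect_setequal(full$label, hli_labels())
  expect_identical(sort(full$healthiness_rank), 1:9)
  expect_error(combine_hli(0, 2), "1..3")
})

test_that("the full pipeline reproduces the frozen hand fixture", {
  acc <- data.frame(
    meshblock_id = letters[1:10],
    green = c(2.97, 0.66, 3.45, 4.96, 2.72, 4.84, 3.39, 1.54, 1.86, 0.96),
    blue = c(2.79, 2.58, 1.05, 3.22, 3.47, 3.24, 1.85, 0.6, 0.58, 1),
    physical_activity = c(1.22, 0.49, 4.13, 3, 3.89, 1.82, 0.13, 4.09, 0.11, 1.08),
    supermarket = c(2.55, 1.69, 1.8, 2.77, 0.3, 2.27, 3.49, 4.14, 3.07, 4.89),
    fruit_veg = c(4.33, 2.46, 3.89, 4.66, 2.43, 4.59, 1.89, 2.19, 2.98, 0.64),
    fast_food = c(3.58, 4.11, 3.79, 4.9, 1.53, 4.29, 0.52, 2.79, 4.6, 2),
    takeaway = c(4.58, 1.51, 3.4, 3.7, 2.27, 4.26, 2.8, 4.62, 0.15, 4.22),
    dairy_convenience = c(0.52, 3.21, 2.17, 2.11, 2.68, 0.54, 2.73, 0.68, 3.17, 3.65),
    alcohol = c(2.81, 3.27, 0.33, 2.92, 2.01, 0.79, 0.4, 1.65, 0.51, 4.14),
    gaming = c(0.53, 4.23, 0.97, 2.51, 1.05, 1.15, 4.76, 2.48, 2.25, 0.18),
    stringsAsFactors = FALSE)
  ix <- compute_hli(acc)
  expect_identical(ix$records$label,
                   c("2–1", "1–3", "3–1", "3–3",
                     "2–1", "3–2", "2–2", "2–2",
                     "1–2", "1–3"))
  expect_identical(ix$composite$goods_decile,
                   c(7L, 1L, 8L, 10L, 6L, 9L, 4L, 5L, 2L, 3L))
  expect_identical(ix$composite$bads_decile,
                   c(3L, 9L, 1L, 10L, 2L, 5L, 4L, 7L, 6L, 8L))
})

test_that("pipeline output equals the independent naive implementation", {
  acc <- random_access(100, seed = 31)
  ix <- compute_hli(acc)
  o <- ora_hli(acc)
  for (col in c("goods_rank_sum", "bads_rank_sum", "goods_rank", "bads_rank",
                "goods_decile", "bads_decile"))
    expect_identical(ix$composite[[col]], o[[col]])
  expect_identical(ix$records$goods_category, o$goods_category)
  expect_identical(ix$records$bads_category, o$bads_category)
  expect_identical(ix$records$label, o$label)
})

test_that("outputs are invariant to strictly increasing transforms of one domain", {
  acc <- random_access(120, seed = 12)
  ix1 <- compute_hli(acc)
  acc2 <- acc
  acc2$alcohol <- acc2$alcohol^2
  ix2 <- compute_hli(acc2)
  expect_identical(ix1$ranks, ix2$ranks)
  expect_identical(ix1$composite, ix2$composite)
  expect_identical(ix1$records, ix2$records)
})

test_that("duplicating rows changes N but survives the rerun oracle; originals shift at most one decile", {
  acc <- random_access(40, seed = 17)
  dup <- acc
  dup$meshblock_id <- paste0(dup$meshblock_id, "zz")
  both <- rbind(acc, dup)
  ix <- compute_hli(both)
  o <- ora_hli(both)
  expect_identical(ix$composite$goods_decile, o$goods_decile)
  expect_identical(ix$records$label, o$label)
  orig <- compute_hli(acc)
  expect_true(all(abs(ix$composite$goods_decile[1:40] -
                      orig$composite$goods_decile) <= 1))
})

test_that("improving one good-domain distance never worsens the goods decile", {
  acc <- random_access(80, seed = 23)
  base <- compute_hli(acc)
  set.seed(24)
  for (rep in 1:20) {
    i <- sample(80, 1)
    acc2 <- acc
    acc2$green[i] <- acc2$green[i] * runif(1, 0.05, 0.95)
    ix <- compute_hli(acc2)
    expect_lte(ix$composite$goods_decile[i], base$composite$goods_decile[i])
  }
})

test_that("decile and category counts are conserved", {
  acc <- random_access(137, seed = 40)
  ix <- compute_hli(acc)
  for (side in c("goods", "bads")) {
    dec <- ix$composite[[paste0(side, "_decile")]]
    cat3 <- ix$records[[paste0(side, "_category")]]
    expect_lte(diff(range(table(dec))), 1)
    expect_identical(sum(dec %in% 1:3), sum(cat3 == 1L))
    expect_identical(sum(dec %in% 4:7), sum(cat3 == 2L))
    expect_identical(sum(dec %in% 8:10), sum(cat3 == 3L))
  }
})
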