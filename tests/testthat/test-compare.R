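test_that("call-set filtering applies both thresholds", {
  cs <- callset(data.frame(pos = c(10, 20, 30), ref = "A", alt = "G",
                           af = c(0.05, 0.02, 0.05),
                           total = c(100, 100, 40)), "c1")
  f <- filter_callset(cs, af_min = 0.03, depth_min = 50)
  expect_equal(f$variants$pos, 10)  # AF 0.02 removed; depth 40 removed
})

test_that("pairwise concordance performs the documented set arithmetic", {
  a <- mk_callset(c(1, 2, 3), "a")
  b <- mk_callset(c(2, 3, 4), "b")
  bulk <- mk_callset(2, "bulk", assay = "BULK")
  pc <- pairwise_concordance(a, b, bulk, af_min = 0.03, depth_min = 50)
  expect_equal(pc$all, 4)
  expect_equal(pc$common, 2)
  expect_equal(pc$pct_common, 50)
  expect_equal(pc$unique, 2)
  expect_equal(pc$confirmed, 1)
  expect_equal(pc$pct_confirmed, 50)
  expect_equal(pc$hom, 2)  # AF 1 on both sides
  expect_equal(pc$het, 0)

  # disjoint call sets: degenerate, percentages reported as 0 with a flag
  d <- pairwise_concordance(mk_callset(1:3, "a"), mk_callset(4:6, "b"),
                            bulk)
  expect_equal(d$common, 0)
  expect_equal(d$pct_common, 0)
  expect_equal(d$pct_confirmed, 0)
  expect_true(d$degenerate)
})

test_that("published eWGA pair counts reproduce through the same arithmetic", {
  tab <- packaged_table("ht29_pairwise")
  ew <- tab[tab$protocol == "eWGA", ]
  # construct call sets with exactly the published set sizes
  a <- mk_callset(c(1:40, 101:102), "a")       # 40 common + 2 private
  b <- mk_callset(c(1:40, 201:202), "b")
  bulk <- mk_callset(1:36, "bulk", assay = "BULK")
  pc <- pairwise_concordance(a, b, bulk)
  expect_equal(pc$all, ew$all)
  expect_equal(pc$common, ew$common)
  expect_equal(pc$pct_common, ew$pct_common)    # 90.91
  expect_equal(pc$unique, ew$unique)
  expect_equal(pc$confirmed, ew$confirmed)
  expect_equal(pc$pct_confirmed, ew$pct_confirmed)  # 90
})

test_that("pairwise concordance is symmetric and conserves counts", {
  set.seed(91)
  for (i in 1:10) {
    a <- mk_callset(sample(1:60, 30), "a", af = runif(30),
                    total = sample(10:200, 30, replace = TRUE))
    b <- mk_callset(sample(1:60, 30), "b", af = runif(30),
                    total = sample(10:200, 30, replace = TRUE))
    ab <- pairwise_concordance(a, b, af_min = 0.05, depth_min = 30)
    ba <- pairwise_concordance(b, a, af_min = 0.05, depth_min = 30)
    expect_equal(ab$all, ba$all)
    expect_equal(ab$common, ba$common)
    expect_equal(ab$pct_common, ba$pct_common)
    expect_equal(ab$unique + ab$common, ab$all)
    expect_equal(ab$hom + ab$het, ab$common)
  }
})

test_that("PPV treats common variants as true positives per cell", {
  a <- mk_callset(1:10, "a")
  b <- mk_callset(c(1:9, 20), "b")
  pc <- pairwise_concordance(a, b)
  p <- ppv(pc)
  expect_equal(p$ppv_a, 90)
  expect_equal(p$ppv_b, 90)

  same <- pairwise_concordance(a, a)
  expect_equal(ppv(same)$mean, 100)

  disj <- pairwise_concordance(mk_callset(1:3, "a"), mk_callset(5:7, "b"))
  expect_equal(ppv(disj)$mean, 0)
})

test_that("threshold sweeps are monotone and consistent with direct calls", {
  set.seed(92)
  a <- mk_callset(1:50, "a", af = runif(50, 0.01, 1),
                  total = sample(10:1200, 50, replace = TRUE))
  b <- mk_callset(26:75, "b", af = runif(50, 0.01, 1),
                  total = sample(10:1200, 50, replace = TRUE))
  grid <- threshold_grid()
  sw <- threshold_sweep(a, b, grid = grid)
  expect_equal(nrow(sw), length(grid$af) * length(grid$depth))
  for (d in grid$depth) {
    sub <- sw[sw$depth_min == d, ]
    sub <- sub[order(sub$af_min), ]
    expect_true(all(diff(sub$common) <= 0))  # stricter AF never adds commons
  }
  direct <- pairwise_concordance(a, b, af_min = 0.03, depth_min = 50)
  row <- sw[sw$af_min == 0.03 & sw$depth_min == 50, ]
  expect_equal(row$common, direct$common)
  expect_equal(row$pct_common, direct$pct_common)
  expect_error(threshold_grid(af = c(0.1, 0.05)), "ascending")
})

test_that("allele-frequency correlation matches the direct formula", {
  a <- mk_callset(1:3, "a", af = c(0.1, 0.5, 0.9))
  b1 <- mk_callset(1:3, "b", af = c(0.1, 0.5, 0.9))
  expect_equal(af_correlation(a, b1)$r, 1)
  b2 <- mk_callset(1:3, "b", af = c(0.9, 0.5, 0.1))
  expect_equal(af_correlation(a, b2)$r, -1)

  set.seed(93)
  x <- runif(10); y <- x * 0.8 + runif(10, 0, 0.2)
  ca <- mk_callset(1:10, "a", af = x)
  cb <- mk_callset(1:10, "b", af = y)
  got <- af_correlation(ca, cb)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)

  expect_error(af_correlation(mk_callset(1:2, "a"), mk_callset(1:2, "b")),
               "at least 3")
})

test_that("multi-cell tabulation counts cells, bulk support and raw bulk AF", {
  cells <- lapply(1:9, function(i) {
    pos <- if (i <= 5) c(100, 200) else 200
    mk_callset(pos, sprintf("c%d", i))
  })
  # variant at 300 in exactly one cell: excluded at min_cells = 2
  cells[[1]] <- mk_callset(c(100, 200, 300), "c1")
  bulk <- callset(data.frame(pos = c(100, 200), ref = "A", alt = "G",
                             af = c(1, 1), total = c(100, 10)), "bulk", "BULK")
  tab <- tabulate_multicell(cells, bulk, af_min = 0.03, depth_min = 30,
                            min_cells = 2)
  expect_setequal(tab$pos, c(100, 200))
  r100 <- tab[tab$pos == 100, ]
  expect_equal(r100$n_cells_WGS, 5)
  expect_equal(r100$mean_af_WGS, 1)
  expect_equal(r100$in_bulk, 1)
  # bulk depth 10 < 30: not confirmed, but raw bulk AF still reported
  r200 <- tab[tab$pos == 200, ]
  expect_equal(r200$in_bulk, 0)
  expect_equal(r200$bulk_af, 1)
})

test_that("table statistics reproduce the published multi-cell summaries", {
  # single constructed row first
  one <- data.frame(n_cells = 3, mean_af = 0.5, in_bulk = 1)
  s <- table_stats(one, n_cells = 9)
  expect_equal(s$n_hom, 0)
  expect_equal(s$n_het, 1)
  expect_equal(s$pct_bulk_confirmed, 100)

  # nine eWGA-amplified cells, WGS assay
  wgs <- assay_view(packaged_table("ht29_ewga_cells"), "WGS")
  sw <- table_stats(wgs, n_cells = 9)
  expect_equal(sw$n_variants, 44)
  expect_equal(sw$n_hom, 37)
  expect_equal(sw$n_het, 7)
  expect_equal(sw$het_af_min, 0.06)
  expect_equal(sw$het_af_max, 0.38)
  expect_equal(sw$pct_bulk_confirmed, 77)
  expect_equal(sw$pct_shared_by_majority, 82)

  # same cells, WES assay
  wes <- assay_view(packaged_table("ht29_ewga_cells"), "WES")
  se <- table_stats(wes, n_cells = 9)
  expect_equal(se$n_variants, 40)
  expect_equal(se$pct_bulk_confirmed, 85)

  # 48 ATAC-profiled cells
  atac <- assay_view(packaged_table("tf1_atac_cells"), "ATAC")
  sa <- table_stats(atac, n_cells = 48)
  expect_equal(sa$n_variants, 49)
  expect_equal(sa$n_hom, 42)
  expect_equal(sa$n_het, 7)
  expect_equal(sa$het_af_min, 0.04)
  expect_equal(sa$het_af_max, 0.2)
  expect_equal(sa$pct_bulk_confirmed, 90)
  expect_equal(sa$n_majority, 42)

  expect_error(table_stats(one[0, ], 9), "empty")
})
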