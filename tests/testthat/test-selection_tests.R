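test_that("breakpoint-gene overlap respects half-open interval boundaries", {
  genes <- data.frame(arm = "X", start = 100, end = 200, name = "g1")
  arms <- c(X = 1000)
  expect_identical(breakpoint_gene_overlap(data.frame(arm = "X", pos = 150), genes, arms), 1L)
  expect_identical(breakpoint_gene_overlap(data.frame(arm = "X", pos = 200), genes, arms), 0L)
  expect_identical(breakpoint_gene_overlap(data.frame(arm = "X", pos = 100), genes, arms), 1L)
  # flank extends the interval on both sides
  expect_identical(breakpoint_gene_overlap(data.frame(arm = "X", pos = 95), genes, arms,
                                           flank = 10), 1L)
  expect_error(breakpoint_gene_overlap(data.frame(arm = "X", pos = 1500), genes, arms),
               "outside")
  # random sets agree with brute-force membership
  set.seed(801)
  g2 <- data.frame(arm = "X", start = sort(sample(0:900, 10)) , name = paste0("g", 1:10))
  g2$end <- g2$start + 20
  pos <- sample(0:999, 50)
  oracle <- sum(vapply(pos, function(p) any(p >= g2$start & p < g2$end), logical(1)))
  expect_identical(breakpoint_gene_overlap(data.frame(arm = "X", pos = pos), g2, arms),
                   oracle)
})

test_that("permutation p-values use the add-one rule and match the binomial null", {
  genes <- data.frame(arm = "X", start = 0, end = 1000, name = "g1")  # whole arm genic
  bp <- data.frame(arm = "X", pos = 500)
  pt <- breakpoint_permutation_test(bp, genes, c(X = 1000), B = 200)
  expect_identical(pt$observed_overlap, 1L)
  expect_equal(pt$p_value, 1)  # every null draw also overlaps
  expect_true(all(pt$null_draws == 1L))
  # paired permutation keeps spacing on the arm
  set.seed(802)
  genes2 <- data.frame(arm = "X", start = 0, end = 300, name = "g1")
  bp2 <- data.frame(arm = "X", pos = c(400, 900))
  pt2 <- breakpoint_permutation_test(bp2, genes2, c(X = 1000), B = 500,
                                     preserve_pairs = c(1, 1))
  expect_lte(max(pt2$null_draws), 2L)
})

test_that("the exact binomial distortion test reproduces its anchors", {
  ga <- sex_ratio_test(781, 1451 - 781)
  expect_equal(round(ga$K, 3), 0.538)
  expect_equal(round(ga$p, 6), 0.001933)
  even <- sex_ratio_test(50, 50)
  expect_equal(even$K, 0.5)
  expect_equal(round(even$p, 3), 0.540)
  expect_equal(sex_ratio_test(5, 0)$p, 0.5^5)
  expect_error(sex_ratio_test(0, 0), "zero progeny")
  # brute-force tail sum oracle on small cases
  set.seed(803)
  for (i in 1:10) {
    n <- sample(5:30, 1); f <- sample(0:n, 1)
    if (f + (n - f) == 0) next
    oracle <- sum(stats::dbinom(f:n, n, 0.5))
    expect_equal(sex_ratio_test(f, n - f)$p, oracle, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(round(bonferroni_adjust(0.001933, 11), 5), 0.02126)
  expect_lt(bonferroni_adjust(0.001933, 11), 0.05)
  expect_equal(bonferroni_adjust(0.02, 11), 0.22)
  expect_equal(bonferroni_adjust(0.2, 11), 1)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), ">=")
})

test_that("the conservative egg test attributes all mortality to males", {
  egg <- conservative_egg_test(2724, 1428)
  expect_equal(round(egg$K, 3), 0.524)
  half <- conservative_egg_test(1000, 500)
  expect_equal(half$K, 0.5)
  expect_gt(half$p, 0.4)
  expect_error(conservative_egg_test(100, 150), "exceed")
  # equals the plain binomial with the assumed male count
  expect_equal(conservative_egg_test(2724, 1428)$p,
               sex_ratio_test(1428, 2724 - 1428)$p)
})

test_that("cross summaries reproduce the published table averages", {
  tab <- inbe_crosses()
  expect_identical(nrow(tab), 20L)
  cs <- cross_summary(tab)
  expt <- cs[cs$role == "experimental", ]
  ctl <- cs[cs$role == "control", ]
  expect_lt(abs(expt$mean_progeny - 733.72), 0.01)
  expect_equal(round(expt$mean_f1_males, 2), 6.27)
  expect_equal(round(expt$mean_K, 3), 0.541)
  expect_equal(round(ctl$mean_K, 3), 0.511)
  expect_lt(abs(ctl$mean_progeny - 535.67), 0.01)
  expect_equal(round(ctl$mean_f1_males, 2), 5.56)
  # single record: its own values
  one <- cross_summary(data.frame(role = "experimental", f1_males = 3,
                                  females = 60, males = 40))
  expect_equal(one$mean_K, 0.6)
})

test_that("cross tables round-trip through TSV with validation", {
  tab <- inbe_crosses()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cross_records(path)
  expect_equal(back$females, tab$females)
  bad <- tab
  bad$eggs[1] <- 10
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cross_records(path), "exceed egg")
})
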