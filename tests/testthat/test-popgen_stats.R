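test_that("summary statistics reproduce the worked four-haplotype example", {
  a <- inv_alignment(c("AAA", "AAT", "ATA", "TAA"))
  s <- stats_suite(a, "complete")
  expect_identical(s$S, 3L)
  expect_equal(s$pi_region, 1.5)
  expect_equal(s$theta_w_region, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  # frozen from an independent evaluation of the variance constants
  expect_equal(s$tajima_d, -0.7544511, tolerance = 1e-6)
  expect_equal(s$d_prime, -1)  # all sites already singletons: D equals D_min
})

test_that("monomorphic and undersized alignments are handled as contracts state", {
  mono <- inv_alignment(c("ACGT", "ACGT", "ACGT"))
  s <- stats_suite(mono)
  expect_identical(s$S, 0L)
  expect_identical(s$pi_region, 0)
  expect_true(is.na(s$tajima_d) && is.na(s$d_prime))
  expect_error(stats_suite(inv_alignment("ACGT")), "insufficient-sample")
})

test_that("regional pi equals the mean of pairwise mismatch counts (oracle)", {
  set.seed(201)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    a <- random_alignment(n, 50, p_missing = 0.08)
    cd <- complete_deletion(a)
    if (ncol(cd$mat) == 0) next
    pairs <- utils::combn(n, 2)
    mm <- apply(pairs, 2, function(p) sum(cd$mat[p[1], ] != cd$mat[p[2], ]))
    s <- stats_suite(a, "complete")
    expect_equal(s$pi_region, mean(mm), tolerance = 1e-12)
    expect_identical(s$S, sum(apply(cd$mat, 2, function(col) length(unique(col)) >= 2)))
    # Tajima's D carries the sign of pi - theta_W
    if (s$S > 0 && abs(s$pi_region - s$theta_w_region) > 1e-9) {
      expect_identical(sign(s$tajima_d), sign(s$pi_region - s$theta_w_region))
    }
  }
})

test_that("between-group pi matches brute-force enumeration of cross pairs", {
  set.seed(202)
  a <- random_alignment(5, 40, p_missing = 0.05)
  g1 <- c("s1", "s2", "s3"); g2 <- c("s4", "s5")
  res <- between_group_pi(a, g1, g2, "complete")
  cd <- complete_deletion(subset_alignment(a, c(g1, g2)))
  mm <- as.vector(outer(g1, g2, Vectorize(function(i, j) sum(cd$mat[i, ] != cd$mat[j, ]))))
  expect_equal(res$pi_region, mean(mm), tolerance = 1e-12)
  # trivial anchors
  ident <- inv_alignment(c("ACGT", "ACGT", "ACGT"), sample_ids = c("x", "y", "z"))
  expect_identical(between_group_pi(ident, c("x", "y"), "z")$pi_region, 0)
  fixed <- inv_alignment(c("AAAA", "TAAA"), sample_ids = c("x", "y"))
  expect_equal(between_group_pi(fixed, "x", "y")$pi_site, 1 / 4)
  expect_error(between_group_pi(a, character(), g2), "non-empty")
})

test_that("Hudson's F_ST reproduces the hand-enumerated example and edge behavior", {
  a <- inv_alignment(c("A", "A", "T", "T", "T"), sample_ids = paste0("s", 1:5))
  res <- hudson_fst(a, c("s1", "s2", "s3"), c("s4", "s5"))
  expect_equal(res$fst, 0.5)  # pi1 = 2/3, pi2 = 0, Hw = 1/3, Hb = 2/3
  # fixed differences at every site give 1
  b <- inv_alignment(c("AAA", "AAA", "TTT", "TTT"), sample_ids = paste0("s", 1:4))
  expect_equal(hudson_fst(b, c("s1", "s2"), c("s3", "s4"))$fst, 1)
  # negative estimates are reported as computed, with a flag (disjoint
  # duplicate groups make H_b < H_w in finite samples)
  cc <- inv_alignment(c("AT", "TA", "AT", "TA"), sample_ids = paste0("s", 1:4))
  same <- hudson_fst(cc, c("s1", "s2"), c("s3", "s4"))
  expect_true(same$negative)
  expect_equal(same$fst, -1)
  # monomorphic data: undefined flag, no division by zero
  mono <- inv_alignment(rep("AAAA", 4), sample_ids = paste0("s", 1:4))
  expect_true(hudson_fst(mono, c("s1", "s2"), c("s3", "s4"))$undefined)
  expect_error(hudson_fst(a, "s1", c("s4", "s5")), ">= 2")
})

test_that("windowed scans tile without losing segregating sites", {
  set.seed(203)
  cfg <- scenario_config(age_years = 50000, L = 8000, exchange_rate = 0)
  a <- generate_breakpoint_region(cfg)$alignment
  total_S <- stats_suite(a, "pairwise")$S
  for (mode in c("fixed_bp", "seg_sites")) {
    w <- if (mode == "fixed_bp") 2500 else 40
    ws <- window_scan(a, mode, width = w, statistic = "pi")
    expect_identical(sum(ws$S), total_S)
    expect_identical(ws$start[1], 0L)
    expect_identical(ws$end[nrow(ws)], alignment_length(a))
    expect_true(all(ws$start[-1] == ws$end[-nrow(ws)]))  # non-overlapping tiling
    if (mode == "seg_sites") {
      expect_true(all(ws$S[-nrow(ws)] == 40))  # full windows close at exactly `width`
      expect_lte(ws$S[nrow(ws)], 40)
    }
  }
})

test_that("pairwise divergence counts aligned bases the way the QC table does", {
  p <- pair_with_counts(52099, 568)
  d <- divergence_pair(p$s1, p$s2)
  expect_identical(d$mismatches, 568L)
  expect_equal(round(d$proportion, 4), 0.0109)
  expect_identical(divergence_pair("ACGT", "ACGT")$mismatches, 0L)
  # masked columns drop out of the aligned-base count
  pm <- pair_with_counts(30, 0, masked = 5)
  expect_identical(divergence_pair(pm$s1, pm$s2)$aligned_bases, 30L)
  expect_true(divergence_pair("NNN", "ACG")$undefined)
  expect_error(divergence_pair("ACG", "AC"), "equal length")
})
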