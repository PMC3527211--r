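test_that("group divergence and nearest neighbor match brute-force oracles", {
  set.seed(601)
  mat <- matrix(sample(c("A", "C", "G", "T"), 7 * 60, replace = TRUE), 7,
                dimnames = list(c("i1", "i2", "f1", "f2", "r1", "r2", "r3"), NULL))
  meta <- data.frame(sample_id = rownames(mat),
                     population = c("RG", "RG", "FR", "FR", "RG", "RG", "RG"),
                     arm = "X", inv1 = c("inverted", "inverted", rep("standard", 5)),
                     stringsAsFactors = FALSE)
  a <- inv_alignment(mat, meta = meta)
  inv <- c("i1", "i2"); stds <- c("f1", "f2", "r1", "r2", "r3")
  # oracle: enumerate every inverted x standard per-site proportion
  div <- outer(inv, stds, Vectorize(function(i, g) mean(mat[i, ] != mat[g, ])))
  expect_equal(mean_divergence_to_group(a, inv, stds), mean(div), tolerance = 1e-12)
  nn <- nearest_neighbor(a, inv, stds)
  expect_identical(nn$sample_id, stds[which.min(apply(div, 2, min))])
  # an exact match wins with divergence zero
  mat2 <- mat; mat2["f1", ] <- mat2["i1", ]
  a2 <- inv_alignment(mat2, meta = meta)
  nn2 <- nearest_neighbor(a2, inv, stds)
  expect_identical(nn2$sample_id, "f1")
  expect_equal(nn2$divergence, 0)
})

test_that("the two-condition rule and tie escalation drive the call", {
  L <- 60
  close_seq <- rep("A", L)
  far_seq <- c(rep("T", 12), rep("A", L - 12))
  mid_seq <- c(rep("G", 6), rep("A", L - 6))
  mk <- function(rows, pops, arrangements) {
    mat <- do.call(rbind, rows)
    meta <- data.frame(sample_id = rownames(mat), population = pops, arm = "X",
                       inv1 = arrangements, stringsAsFactors = FALSE)
    inv_alignment(mat, meta = meta)
  }
  # inverted nearly identical to the cosmopolitan standards -> Cosmopolitan
  a <- mk(list(i1 = close_seq, i2 = close_seq, f1 = close_seq, f2 = mid_seq,
               r1 = far_seq, r2 = far_seq),
          c("RG", "RG", "FR", "FR", "RG", "RG"),
          c("inverted", "inverted", rep("standard", 4)))
  rep1 <- classify_origin_breakpoint(a, c("i1", "i2"), c("f1", "f2"), c("r1", "r2"))
  expect_identical(rep1$call, "Cosmopolitan")
  # nearest neighbor African even though mean French divergence is smaller -> African
  b <- mk(list(i1 = close_seq, i2 = close_seq, f1 = mid_seq, f2 = mid_seq,
               r1 = close_seq, r2 = far_seq, r3 = far_seq),
          c("RG", "RG", "FR", "FR", "RG", "RG", "RG"),
          c("inverted", "inverted", rep("standard", 5)))
  rep2 <- classify_origin_breakpoint(b, c("i1", "i2"), c("f1", "f2"),
                                     c("r1", "r2", "r3"))
  expect_identical(rep2$call, "African")
  # equal-divergence tie between a French and an African neighbor -> Ambiguous
  d <- mk(list(i1 = close_seq, f1 = mid_seq, r1 = mid_seq, r2 = far_seq),
          c("RG", "FR", "RG", "RG"),
          c("inverted", rep("standard", 3)))
  rep3 <- classify_origin_breakpoint(d, "i1", "f1", c("r1", "r2"))
  expect_identical(rep3$call, "Ambiguous")
})

test_that("classification is invariant to sample order and reference duplication", {
  set.seed(602)
  cfg <- scenario_config(age_years = 3000, origin = "African")
  g <- generate_breakpoint_region(cfg)
  a <- g$alignment
  inv <- a$meta$sample_id[a$meta$inv1 == "inverted"]
  afr <- a$meta$sample_id[a$meta$inv1 == "standard" & a$meta$population == "RG"]
  cos <- a$meta$sample_id[a$meta$inv1 == "standard" & a$meta$population == "FR"]
  r1 <- classify_origin_breakpoint(a, inv, cos, afr)
  r2 <- classify_origin_breakpoint(a, rev(inv), rev(cos), rev(afr))
  expect_identical(r1$call, r2$call)
  # duplicating a reference haplotype must not change the call
  dup <- a
  dup$mat <- rbind(dup$mat, dup2 = dup$mat[afr[1], ])
  dup$meta <- rbind(dup$meta, data.frame(sample_id = "dup2", population = "RG",
                                         arm = "arm1", inv1 = "standard"))
  r3 <- classify_origin_breakpoint(dup, inv, cos, c(afr, "dup2"))
  expect_identical(r1$call, r3$call)
})

test_that("per-breakpoint calls combine by unanimity", {
  mkrep <- function(call) structure(list(call = call), class = "origin_report")
  expect_identical(classify_origin(list(mkrep("African"), mkrep("African")))$call,
                   "African")
  expect_identical(classify_origin(list(mkrep("African"), mkrep("Cosmopolitan")))$call,
                   "Ambiguous")
  expect_identical(classify_origin(mkrep("Cosmopolitan"))$call, "Cosmopolitan")
})

test_that("synthetic scenarios with known origins are recovered", {
  # regions of 20 kb carry enough post-bottleneck substitutions to resolve
  # the split; exchange tracts are masked first, as the pipeline prescribes
  calls <- vapply(1:10, function(seed) {
    set.seed(700 + seed)
    origin <- if (seed %% 2) "African" else "Cosmopolitan"
    cfg <- scenario_config(age_years = 3000, origin = origin, L = 20000)
    g <- generate_breakpoint_region(cfg)
    a <- g$alignment
    masks <- detect_exchange_tracts(a, "inv1")
    a <- suppressWarnings(apply_masks(a, masks, inversion = "inv1"))$alignment
    grp <- function(cond) intersect(a$meta$sample_id[cond], rownames(a$mat))
    inv <- grp(a$meta$inv1 == "inverted")
    afr <- grp(a$meta$inv1 == "standard" & a$meta$population == "RG")
    cos <- grp(a$meta$inv1 == "standard" & a$meta$population == "FR")
    if (!length(inv) || !length(afr) || !length(cos)) return(FALSE)
    identical(classify_origin_breakpoint(a, inv, cos, afr)$call, g$ledger$origin)
  }, logical(1))
  expect_gte(sum(calls), 9)
})
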