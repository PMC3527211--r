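test_that("FASTA round-trips exactly over the 6-letter alphabet", {
  set.seed(101)
  a <- random_alignment(4, 25)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(a, path)
  b <- read_fasta_alignment(path)
  expect_identical(b$mat, a$mat)
  expect_identical(rownames(b$mat), rownames(a$mat))
})

test_that("reading enforces alignment shape and normalizes ambiguity codes", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), path)
  expect_error(read_fasta_alignment(path), "alignment-shape")

  writeLines(c(">a", "ACGTRCGTAC", ">b", "acgtacgtac"), path)
  expect_warning(a <- read_fasta_alignment(path), "converted to N")
  expect_identical(unname(a$mat["a", 5]), "N")  # R -> N
  expect_identical(unname(a$mat["b", 1]), "A")  # lowercase uppercased
  expect_error(inv_alignment("ACXT"), "alphabet error")
})

test_that("complete deletion matches a brute-force column scan and is idempotent", {
  expect_identical(
    apply(complete_deletion(inv_alignment(c("AC-T", "ACGT")))$mat, 1, paste, collapse = ""),
    c(sample1 = "ACT", sample2 = "ACT")
  )
  set.seed(102)
  for (i in 1:10) {
    a <- random_alignment(4, 40, p_missing = 0.15)
    keep <- which(apply(a$mat, 2, function(col) all(col %in% c("A", "C", "G", "T"))))
    cd <- complete_deletion(a)
    expect_identical(cd$mat, a$mat[, keep, drop = FALSE])
    expect_identical(cd$col_map, keep)
    expect_identical(complete_deletion(cd)$mat, cd$mat)  # idempotent
  }
  clean <- inv_alignment(c("ACGT", "ACGT"))
  expect_identical(complete_deletion(clean)$mat, clean$mat)
  expect_warning(complete_deletion(inv_alignment(c("-N", "NN"))), "every column")
})

test_that("subsetting preserves order, composes, and interacts with deletion as expected", {
  set.seed(103)
  a <- random_alignment(5, 30)
  expect_identical(subset_alignment(a)$mat, a$mat)
  s2 <- subset_alignment(a, c("s4", "s2"))
  expect_identical(rownames(s2$mat), c("s4", "s2"))
  expect_error(subset_alignment(a, "nope"), "unknown sample")
  # nested subsets compose
  x <- c("s1", "s3", "s5"); y <- c("s5", "s1")
  expect_identical(subset_alignment(subset_alignment(a, x), y)$mat,
                   subset_alignment(a, y)$mat)
  # masking fewer samples never reveals columns
  for (i in 1:5) {
    a <- random_alignment(6, 40, p_missing = 0.2)
    sub <- c("s1", "s2", "s3")
    n_sub_first <- ncol(complete_deletion(subset_alignment(a, sub))$mat)
    n_del_first <- ncol(subset_alignment(complete_deletion(a), sub)$mat)
    expect_gte(n_sub_first, n_del_first)
  }
})

test_that("metadata validation restricts arrangement labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\tarm\tinv1",
               "s1\tRG\tX\tinverted", "s2\tFR\tX\tstandard"), path)
  meta <- read_sample_meta(path)
  expect_identical(meta$inv1, c("inverted", "standard"))
  writeLines(c("sample_id\tpopulation\tarm\tinv1", "s1\tRG\tX\thet"), path)
  expect_error(read_sample_meta(path), "arrangement labels")
})

test_that("residual-heterozygosity arm masking equals a longest-run oracle", {
  flat <- data.frame(sample = "s1", arm = "X", window = 1:10, het_fraction = 0)
  expect_identical(nrow(mask_het_arms(flat)), 0L)
  four <- data.frame(sample = "s1", arm = "X", window = 1:10,
                     het_fraction = c(0, 0, 0.01, 0.01, 0.01, 0.01, 0, 0, 0, 0))
  expect_identical(mask_het_arms(four)$longest_run, 4L)
  set.seed(104)
  for (i in 1:20) {
    het <- data.frame(sample = "s", arm = "a", window = 1:30,
                      het_fraction = stats::runif(30, 0, 0.01))
    flagged <- nrow(mask_het_arms(het, run_threshold = 3, het_fraction_cut = 0.005)) > 0
    runs <- rle(het$het_fraction > 0.005)
    oracle <- any(runs$lengths[runs$values] >= 3)
    expect_identical(flagged, oracle)
  }
})

test_that("interval tables convert losslessly between 0-based and GRanges", {
  df <- data.frame(arm = c("X", "2L"), start = c(0L, 100L), end = c(50L, 200L),
                   name = c("g1", "g2"), stringsAsFactors = FALSE)
  back <- granges_to_intervals(intervals_to_granges(df))
  expect_identical(back$start, df$start)
  expect_identical(back$end, df$end)
  # BED written on disk reads back to the same 0-based coordinates
  path <- withr::local_tempfile(fileext = ".bed")
  utils::write.table(df[, c("arm", "start", "end", "name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gr <- read_intervals(path)
  expect_identical(granges_to_intervals(gr)$start, df$start)
  expect_identical(granges_to_intervals(gr)$end, df$end)
})
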