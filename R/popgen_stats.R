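#' Tajima's variance constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants used to normalize the
#' difference between pairwise diversity and Watterson's estimator.
#'
#' @param n haplotype sample size (>= 2)
#' @return named list of constants
#' @keywords internal
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

is_base <- function(x) x == "A" | x == "C" | x == "G" | x == "T"

# segregating-site count: columns with >= 2 distinct observed bases
count_segregating <- function(mat) {
  sum(apply(mat, 2L, function(col) {
    b <- col[is_base(col)]
    length(unique(b)) >= 2L
  }))
}

# mismatch counts for every unordered pair; pairwise deletion per pair
pair_mismatch_matrix <- function(mat) {
  n <- nrow(mat)
  mm <- matrix(0, n, n)
  len <- matrix(0, n, n)
  base <- is_base(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- base[i, ] & base[j, ]
      mm[i, j] <- mm[j, i] <- sum(mat[i, ok] != mat[j, ok])
      len[i, j] <- len[j, i] <- sum(ok)
    }
  }
  list(mismatch = mm, aligned = len)
}

#' Summary statistics for one alignment
#'
#' Computes the standard single-region summary statistics: the number of
#' segregating sites S, nucleotide diversity (pi, per region and per site),
#' Watterson's theta, Tajima's D, and D' (D rescaled by its theoretical
#' minimum, attained when all S sites are singletons).
#'
#' @param a an [inv_alignment()] with at least 2 haplotypes
#' @param deletion_mode `"complete"` removes every column containing a gap or
#'   N before any computation (the policy used for breakpoint-region
#'   analyses); `"pairwise"` drops missing data per pair/column, applying no
#'   sampling threshold (the policy used for genome-scan diversity).
#' @return list of class `inv_sumstats` with fields `n`, `L`, `S`,
#'   `pi_region`, `pi_site`, `theta_w_region`, `theta_w_site`, `tajima_d`,
#'   `d_prime`, `deletion_mode`.  `tajima_d` and `d_prime` are `NA` (flagged
#'   undefined) when S = 0.
#' @export
stats_suite <- function(a, deletion_mode = c("complete", "pairwise")) {
  deletion_mode <- match.arg(deletion_mode)
  n <- nrow(a$mat)
  if (n < 2) stop("insufficient-sample error: need >= 2 haplotypes")
  mat <- if (deletion_mode == "complete") complete_deletion(a)$mat else a$mat
  L <- ncol(mat)
  S <- if (L) count_segregating(mat) else 0L
  if (L == 0 || S == 0) {
    pm <- list(region = 0, site = 0)
  } else {
    pw <- pair_mismatch_matrix(mat)
    upper <- upper.tri(pw$mismatch)
    pi_region <- mean(pw$mismatch[upper])
    ok <- pw$aligned[upper] > 0
    pi_site <- mean((pw$mismatch[upper] / pw$aligned[upper])[ok])
    pm <- list(region = pi_region, site = pi_site)
  }
  k <- tajima_constants(n)
  theta_w_region <- S / k$a1
  res <- list(
    n = n, L = L, S = S,
    pi_region = pm$region, pi_site = pm$site,
    theta_w_region = theta_w_region,
    theta_w_site = if (L) theta_w_region / L else NA_real_,
    tajima_d = NA_real_, d_prime = NA_real_,
    deletion_mode = deletion_mode
  )
  if (S > 0) {
    denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    res$tajima_d <- (pm$region - theta_w_region) / denom
    # theoretical minimum: all S sites singletons -> pi = 2S/n
    d_min <- (2 * S / n - theta_w_region) / denom
    res$d_prime <- res$tajima_d / abs(d_min)
  }
  class(res) <- "inv_sumstats"
  res
}

#' @export
print.inv_sumstats <- function(x, ...) {
  cat(sprintf(
    "n=%d L=%d S=%d pi_region=%.4f pi_site=%.6f theta_w=%.4f D=%s D'=%s [%s deletion]\n",
    x$n, x$L, x$S, x$pi_region, x$pi_site, x$theta_w_region,
    ifelse(is.na(x$tajima_d), "NA", sprintf("%.3f", x$tajima_d)),
    ifelse(is.na(x$d_prime), "NA", sprintf("%.3f", x$d_prime)),
    x$deletion_mode
  ))
  invisible(x)
}

#' Mean pairwise divergence between two groups of haplotypes
#'
#' Averages mismatch counts (and per-site proportions) over all cross-group
#' pairs, e.g. inverted vs standard haplotypes at a breakpoint region.
#'
#' @param a an [inv_alignment()]
#' @param group1,group2 disjoint character vectors of sample ids
#' @param deletion_mode see [stats_suite()]
#' @return list with `pi_region` (mean mismatch count per cross pair) and
#'   `pi_site` (mean per-site proportion)
#' @export
between_group_pi <- function(a, group1, group2,
                             deletion_mode = c("complete", "pairwise")) {
  deletion_mode <- match.arg(deletion_mode)
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  sub <- subset_alignment(a, c(group1, group2))
  mat <- if (deletion_mode == "complete") complete_deletion(sub)$mat else sub$mat
  i1 <- match(group1, rownames(mat))
  i2 <- match(group2, rownames(mat))
  base <- is_base(mat)
  mm <- numeric(0); pp <- numeric(0)
  for (i in i1) {
    for (j in i2) {
      ok <- base[i, ] & base[j, ]
      d <- sum(mat[i, ok] != mat[j, ok])
      mm <- c(mm, d)
      pp <- c(pp, if (sum(ok)) d / sum(ok) else NA_real_)
    }
  }
  list(pi_region = mean(mm), pi_site = mean(pp, na.rm = TRUE))
}

#' Hudson's F_ST between two groups (unweighted)
#'
#' F_ST = 1 - H_w / H_b with H_w the unweighted mean of the two within-group
#' per-site diversities (no weighting by sample size) and H_b the
#' between-group per-site diversity.  Negative values are reported as
#' computed, with a flag; when H_b = 0 the statistic is undefined.
#'
#' @param a an [inv_alignment()]
#' @param group1,group2 sample id vectors, each of size >= 2
#' @param deletion_mode see [stats_suite()]
#' @return list with `fst`, `h_within`, `h_between`, and logical flags
#'   `undefined` (H_b = 0) and `negative`
#' @export
hudson_fst <- function(a, group1, group2,
                       deletion_mode = c("complete", "pairwise")) {
  deletion_mode <- match.arg(deletion_mode)
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs >= 2 haplotypes")
  }
  sub <- subset_alignment(a, c(group1, group2))
  if (deletion_mode == "complete") sub <- complete_deletion(sub)
  pi1 <- stats_suite(subset_alignment(sub, group1), "pairwise")$pi_site
  pi2 <- stats_suite(subset_alignment(sub, group2), "pairwise")$pi_site
  hb <- between_group_pi(sub, group1, group2, "pairwise")$pi_site
  hw <- (pi1 + pi2) / 2
  if (hb == 0) {
    return(list(fst = NA_real_, h_within = hw, h_between = hb,
                undefined = TRUE, negative = FALSE))
  }
  fst <- 1 - hw / hb
  list(fst = fst, h_within = hw, h_between = hb,
       undefined = FALSE, negative = fst < 0)
}

#' Windowed scans of diversity or differentiation
#'
#' Tiles the alignment with non-overlapping windows, either of fixed physical
#' width (`fixed_bp`, default 250 kb) or containing a fixed number of
#' segregating sites (`seg_sites`, default 1000; the last window may be
#' short), and evaluates pi or Hudson's F_ST in each.
#'
#' @param a an [inv_alignment()]
#' @param mode `"fixed_bp"` or `"seg_sites"`
#' @param width window width: base pairs (fixed_bp) or segregating sites
#'   (seg_sites)
#' @param statistic `"pi"` (per-site, pairwise deletion, no sampling
#'   threshold) or `"fst"`
#' @param group1,group2 sample ids, required for `statistic = "fst"`
#' @return data.frame with columns `start`, `end` (alignment columns, 0-based
#'   half-open), `S`, and `value`
#' @export
window_scan <- function(a, mode = c("fixed_bp", "seg_sites"),
                        width = if (match.arg(mode) == "fixed_bp") 250000L else 1000L,
                        statistic = c("pi", "fst"),
                        group1 = NULL, group2 = NULL) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  L <- ncol(a$mat)
  seg <- apply(a$mat, 2L, function(col) {
    b <- col[is_base(col)]
    length(unique(b)) >= 2L
  })
  if (mode == "fixed_bp") {
    starts <- as.integer(seq(0, L - 1, by = width))
    ends <- as.integer(pmin(starts + width, L))
  } else {
    cum <- cumsum(seg)
    total <- cum[L]
    if (total == 0) {
      starts <- 0L; ends <- L
    } else {
      # window closes after accumulating exactly `width` segregating sites
      nwin <- ceiling(total / width)
      ends <- integer(nwin); starts <- integer(nwin)
      prev <- 0L
      for (w in seq_len(nwin)) {
        target <- min(w * width, total)
        endcol <- which(cum >= target)[1]
        starts[w] <- prev
        ends[w] <- as.integer(endcol)
        prev <- as.integer(endcol)
      }
      ends[nwin] <- as.integer(L)
    }
  }
  value <- numeric(length(starts))
  Sw <- integer(length(starts))
  for (w in seq_along(starts)) {
    win <- subset_alignment(a, interval = c(starts[w], ends[w]))
    Sw[w] <- sum(seg[(starts[w] + 1L):ends[w]])
    value[w] <- if (statistic == "pi") {
      stats_suite(win, "pairwise")$pi_site
    } else {
      hudson_fst(win, group1, group2, "pairwise")$fst
    }
  }
  data.frame(start = starts, end = ends, S = Sw, value = value)
}

#' Divergence between two pre-aligned sequences
#'
#' Counts columns where both characters are unambiguous bases
#' (`aligned_bases`), the number that differ (`mismatches`), and their ratio
#' — the per-site divergence used throughout the assembly-validation
#' arithmetic.
#'
#' @param s1,s2 equal-length sequence strings or character vectors
#' @return list with `aligned_bases`, `mismatches`, `proportion` (`NA` with
#'   `undefined = TRUE` when no column is comparable)
#' @export
divergence_pair <- function(s1, s2) {
  v1 <- if (length(s1) == 1L) strsplit(toupper(s1), "")[[1]] else toupper(s1)
  v2 <- if (length(s2) == 1L) strsplit(toupper(s2), "")[[1]] else toupper(s2)
  if (length(v1) != length(v2)) stop("sequences must have equal length")
  ok <- is_base(v1) & is_base(v2)
  aligned <- sum(ok)
  mism <- sum(v1[ok] != v2[ok])
  list(
    aligned_bases = aligned, mismatches = mism,
    proportion = if (aligned) mism / aligned else NA_real_,
    undefined = aligned == 0L
  )
}
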