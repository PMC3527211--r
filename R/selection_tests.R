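#' Count breakpoints falling inside (flanked) gene intervals
#'
#' @param breakpoints data.frame with columns `arm`, `pos` (0-based
#'   positions) or `arm`, `start`, `end`
#' @param genes data.frame with `arm`, `start`, `end` (0-based half-open) or
#'   a `GRanges`
#' @param arm_lengths named numeric vector of arm lengths in bp
#' @param flank extension of each gene interval on both sides, in bp
#'   (operationalizes "associated regulatory regions"; default 0)
#' @return integer count of breakpoints within any extended gene interval
#' @export
breakpoint_gene_overlap <- function(breakpoints, genes, arm_lengths, flank = 0L) {
  bp <- normalize_breakpoints(breakpoints)
  genes <- normalize_genes(genes)
  bad <- bp$pos < 0 | bp$pos >= arm_lengths[bp$arm] | !(bp$arm %in% names(arm_lengths))
  if (any(is.na(bad)) || any(bad)) stop("breakpoint outside its declared arm")
  count_in_genes(bp$pos, bp$arm, genes, flank)
}

normalize_breakpoints <- function(breakpoints) {
  if (methods::is(breakpoints, "GRanges")) breakpoints <- granges_to_intervals(breakpoints)
  if (!is.null(breakpoints$pos)) {
    data.frame(arm = as.character(breakpoints$arm), pos = breakpoints$pos,
               stringsAsFactors = FALSE)
  } else {
    data.frame(arm = as.character(breakpoints$arm), pos = breakpoints$start,
               stringsAsFactors = FALSE)
  }
}

normalize_genes <- function(genes) {
  if (methods::is(genes, "GRanges")) genes <- granges_to_intervals(genes)
  genes
}

# half-open membership test for point positions, vectorized over points
count_in_genes <- function(pos, arm, genes, flank) {
  hits <- logical(length(pos))
  for (a in unique(arm)) {
    g <- genes[genes$arm == a, , drop = FALSE]
    idx <- which(arm == a)
    if (!nrow(g)) next
    lo <- g$start - flank
    hi <- g$end + flank
    for (i in idx) {
      hits[i] <- any(pos[i] >= lo & pos[i] < hi)
    }
  }
  sum(hits)
}

#' Permutation test for breakpoint-gene overlap
#'
#' Tests whether breakpoints interrupt genic sequence more or less often than
#' expected if they formed uniformly at random along their chromosome arms.
#' Each permutation redraws every breakpoint independently and uniformly on
#' its own arm (optionally preserving the paired distal-proximal spacing of
#' an inversion's two breakpoints) and recounts the overlap.  The p-value
#' uses the add-one estimator, p = (1 + #\{null <= observed\}) / (B + 1) for
#' the lower tail, so it is never zero.
#'
#' @inheritParams breakpoint_gene_overlap
#' @param B number of permutations (>= 1)
#' @param tail `"lower"` (fewer overlaps than expected) or `"upper"`
#' @param preserve_pairs optional integer vector grouping breakpoints into
#'   pairs whose spacing is preserved under permutation (default NULL:
#'   independent placement)
#' @return list of class `perm_test`: `observed_overlap`, `null_draws`,
#'   `p_value`, `B`, `tail`
#' @export
breakpoint_permutation_test <- function(breakpoints, genes, arm_lengths,
                                        B = 100000L, flank = 0L,
                                        tail = c("lower", "upper"),
                                        preserve_pairs = NULL) {
  tail <- match.arg(tail)
  stopifnot(B >= 1)
  bp <- normalize_breakpoints(breakpoints)
  genes <- normalize_genes(genes)
  observed <- breakpoint_gene_overlap(bp, genes, arm_lengths, flank)
  nb <- nrow(bp)
  # per-arm sorted flattened gene boundaries for O(log g) membership
  arm_bounds <- lapply(split(genes, genes$arm), function(g) {
    lo <- sort(g$start - flank)
    hi <- sort(g$end + flank)
    list(lo = lo, hi = hi)
  })
  null_draws <- integer(B)
  if (is.null(preserve_pairs)) {
    pos_mat <- matrix(0, nrow = B, ncol = nb)
    for (j in seq_len(nb)) {
      pos_mat[, j] <- stats::runif(B, 0, arm_lengths[bp$arm[j]])
    }
  } else {
    stopifnot(length(preserve_pairs) == nb)
    pos_mat <- matrix(0, nrow = B, ncol = nb)
    for (grp in unique(preserve_pairs)) {
      idx <- which(preserve_pairs == grp)
      span <- max(bp$pos[idx]) - min(bp$pos[idx])
      arm <- bp$arm[idx[1]]
      anchor <- stats::runif(B, 0, arm_lengths[arm] - span)
      offs <- bp$pos[idx] - min(bp$pos[idx])
      for (k in seq_along(idx)) pos_mat[, idx[k]] <- anchor + offs[k]
    }
  }
  for (j in seq_len(nb)) {
    ab <- arm_bounds[[bp$arm[j]]]
    if (is.null(ab)) next
    # inside some interval iff the latest start <= pos has a matching end > pos
    inside <- in_any_interval(pos_mat[, j], ab$lo, ab$hi)
    null_draws <- null_draws + inside
  }
  p <- if (tail == "lower") {
    (1 + sum(null_draws <= observed)) / (B + 1)
  } else {
    (1 + sum(null_draws >= observed)) / (B + 1)
  }
  structure(list(observed_overlap = observed, null_draws = null_draws,
                 p_value = p, B = B, tail = tail),
            class = "perm_test")
}

# membership in a union of disjoint half-open intervals given sorted bounds
in_any_interval <- function(pos, lo, hi) {
  k <- findInterval(pos, lo)
  inside <- k >= 1L
  inside[inside] <- pos[inside] < hi[k[inside]]
  as.integer(inside)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test (%s tail): observed overlap %d, p = %.6g (B = %d)\n",
              x$tail, x$observed_overlap, x$p_value, x$B))
  invisible(x)
}

#' One-sided exact binomial test for sex-ratio distortion
#'
#' K is the proportion of female progeny; under Mendelian transmission the
#' sex ratio is binomial with probability 1/2, and the p-value is the exact
#' upper-tail probability P(X >= females).
#'
#' @param females,males non-negative progeny counts (total >= 1)
#' @return list with `K` and `p`
#' @export
sex_ratio_test <- function(females, males) {
  n <- females + males
  if (n < 1) stop("zero progeny")
  list(K = females / n,
       p = stats::pbinom(females - 1, n, 0.5, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p-values
#' @param m number of tests (>= length(p_values))
#' @return adjusted p-values, capped at 1
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < length(p_values)) stop("m must be >= number of p-values")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Egg-count bound on distortion assuming all mortality is male
#'
#' Conservative viability control: all pre-adult mortality is attributed to
#' males, so the male count is eggs minus emerged females and the exact
#' binomial test is run on the egg total.
#'
#' @param eggs total eggs laid
#' @param females emerged female count (<= eggs)
#' @return list with `K` (females/eggs) and `p`
#' @export
conservative_egg_test <- function(eggs, females) {
  if (females > eggs) stop("females cannot exceed eggs")
  list(K = females / eggs,
       p = stats::pbinom(females - 1, eggs, 0.5, lower.tail = FALSE))
}

#' Summarize crosses by role
#'
#' Unweighted arithmetic means over crosses (K is averaged across crosses,
#' not pooled over progeny).
#'
#' @param records data.frame with columns `role` (experimental/control),
#'   `f1_males`, `females`, `males`
#' @return data.frame with per-role means of F1 males, total progeny, and K
#' @export
cross_summary <- function(records) {
  stopifnot(all(c("role", "f1_males", "females", "males") %in% names(records)))
  do.call(rbind, lapply(split(records, records$role), function(g) {
    data.frame(
      role = g$role[1],
      n_crosses = nrow(g),
      mean_f1_males = mean(g$f1_males),
      mean_progeny = mean(g$females + g$males),
      mean_K = mean(g$females / (g$females + g$males)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Published In(1)Be distortion cross table
#'
#' The cross table of the In(1)Be sex-ratio experiment, reconstructed from
#' the printed per-cross K and progeny totals: female counts are recovered as
#' round(K * N).  (At the printed precision the RG11N x ZS30 egg-assay row is
#' consistent with either 1428 or 1429 females; 1428 = round(0.541 * 2640) is
#' used.)  The egg count for the RG11N x ZS30 viability assay is carried in
#' the `eggs` column.
#'
#' @return data.frame with columns `x_line`, `y_line`, `f1_males`,
#'   `females`, `males`, `eggs`, `role`
#' @export
inbe_crosses <- function() {
  exp_tab <- data.frame(
    x_line = c("GA191N", "GA191N", "GA191N", "GA191N", "RG10", "RG10",
               "KR39", "KR39", "RG11N", "RG11N", "RG11N"),
    y_line = c("ZS30", "C5", "C17", "K12", "ZS53", "C5",
               "K12", "C17", "C17", "K12", "ZS30"),
    f1_males = c(9, 5, 4, 5, 5, 4, 5, 5, 5, 4, 18),
    progeny = c(1451, 355, 344, 489, 751, 379, 567, 457, 417, 221, 2640),
    K = c(0.538, 0.563, 0.547, 0.517, 0.543, 0.531, 0.526, 0.565,
          0.52, 0.557, 0.541),
    eggs = c(rep(NA_real_, 10), 2724),
    role = "experimental",
    stringsAsFactors = FALSE
  )
  ctl_tab <- data.frame(
    x_line = c("RG11N", "RG22", "RG22", "RG22", "RG35", "RG35",
               "KR42", "KR42", "KR42"),
    y_line = c("ZS30", "C17", "ZS53", "C5", "ZS30", "K12",
               "K12", "C5", "C17"),
    f1_males = c(12, 5, 4, 5, 5, 4, 5, 5, 5),
    progeny = c(1305, 478, 358, 523, 704, 229, 400, 380, 444),
    K = c(0.508, 0.52, 0.495, 0.504, 0.521, 0.546, 0.509, 0.483, 0.511),
    eggs = NA_real_,
    role = "control",
    stringsAsFactors = FALSE
  )
  tab <- rbind(exp_tab, ctl_tab)
  tab$females <- round(tab$K * tab$progeny)
  tab$males <- tab$progeny - tab$females
  tab[, c("x_line", "y_line", "f1_males", "females", "males", "eggs", "role")]
}

#' Read cross progeny counts from TSV
#'
#' Tab-separated with header; requires columns `x_line`, `y_line`,
#' `f1_males`, `females`, `males`, `role`, optionally `eggs`.
#'
#' @param path TSV file path
#' @return data.frame
#' @export
read_cross_records <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("x_line", "y_line", "f1_males", "females", "males", "role")
  if (!all(req %in% names(tab))) {
    stop("cross table must contain columns: ", paste(req, collapse = ", "))
  }
  if (any(tab$females < 0 | tab$males < 0)) stop("negative progeny counts")
  if (!is.null(tab$eggs)) {
    bad <- !is.na(tab$eggs) & tab$females + tab$males > tab$eggs
    if (any(bad)) stop("progeny exceed egg counts in row(s): ",
                       paste(which(bad), collapse = ", "))
  }
  tab
}
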