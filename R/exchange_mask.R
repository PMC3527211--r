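#' Classify polymorphic alignment columns for exchange screening
#'
#' Flags the two signals used to screen breakpoint alignments for genetic
#' exchange between arrangements: polymorphisms shared between inverted and
#' standard classes, and SNPs close to indels (where alignment errors
#' concentrate).  A column is a *shared polymorphism* when it is biallelic
#' and segregates within **both** arrangement classes — a column where the
#' inverted class is monomorphic reflects ancestry of the captured haplotype,
#' not exchange.  A SNP is *indel proximal* when it lies within
#' `indel_window` alignment columns of any gap character.
#'
#' @param a an [inv_alignment()] whose `meta` contains the arrangement column
#' @param inversion name of the metadata column holding
#'   inverted/standard/unknown labels
#' @param indel_window proximity threshold in alignment columns (default 10)
#' @return data.frame with one row per polymorphic column: `col` (1-based
#'   alignment column), `biallelic`, `seg_inverted`, `seg_standard`,
#'   `shared_polymorphism`, `indel_proximal`
#' @export
classify_sites <- function(a, inversion, indel_window = 10L) {
  arr <- get_arrangements(a, inversion)
  inv_rows <- which(arr == "inverted")
  std_rows <- which(arr == "standard")
  if (!length(inv_rows) || !length(std_rows)) {
    stop("both arrangement classes must be present")
  }
  mat <- a$mat
  gap_cols <- which(colSums(mat == "-") > 0L)
  alleles <- function(x) unique(x[is_base(x)])
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    all_a <- alleles(mat[, j])
    if (length(all_a) < 2L) return(NULL)
    inv_a <- alleles(mat[inv_rows, j])
    std_a <- alleles(mat[std_rows, j])
    biallelic <- length(all_a) == 2L
    near_indel <- length(gap_cols) > 0L && min(abs(gap_cols - j)) <= indel_window
    data.frame(
      col = j, biallelic = biallelic,
      seg_inverted = length(inv_a) >= 2L,
      seg_standard = length(std_a) >= 2L,
      shared_polymorphism = biallelic && length(inv_a) >= 2L && length(std_a) >= 2L,
      indel_proximal = near_indel
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(col = integer(), biallelic = logical(),
                      seg_inverted = logical(), seg_standard = logical(),
                      shared_polymorphism = logical(), indel_proximal = logical()))
  }
  do.call(rbind, rows)
}

get_arrangements <- function(a, inversion) {
  if (is.null(a$meta) || !(inversion %in% names(a$meta))) {
    stop("alignment metadata lacks arrangement column '", inversion, "'")
  }
  a$meta[[inversion]][match(rownames(a$mat), a$meta$sample_id)]
}

#' Detect exchange tracts on inverted haplotypes
#'
#' A haplotype segment acquired from the standard arrangement (by double
#' crossover or gene conversion in a heterokaryotype) shows up as a run of
#' shared polymorphisms carried by one inverted haplotype.  For each inverted
#' haplotype, this scans its variant sites (columns where it differs from the
#' inverted-class consensus) in order and reports every maximal run of at
#' least `min_run` consecutive shared-polymorphism alleles as a mask
#' interval.  Because the true exchange boundary is unidentifiable between
#' informative sites, intervals are extended halfway toward the nearest
#' flanking (non-shared) variant site, or to the alignment edge when none
#' exists.
#'
#' @inheritParams classify_sites
#' @param min_run minimum run length (default 3: a shared site flanked by
#'   shared sites on both sides)
#' @return data.frame of mask intervals: `sample_id`, `start`, `end` (0-based
#'   half-open alignment columns), `n_sites`, `reason`
#' @export
detect_exchange_tracts <- function(a, inversion, min_run = 3L, indel_window = 10L) {
  sites <- classify_sites(a, inversion, indel_window)
  arr <- get_arrangements(a, inversion)
  inv_rows <- which(arr == "inverted")
  mat <- a$mat
  L <- ncol(mat)
  shared_cols <- sites$col[sites$shared_polymorphism]
  poly_cols <- sites$col
  # inverted-class consensus base per polymorphic column
  consensus <- vapply(poly_cols, function(j) {
    b <- mat[inv_rows, j]
    b <- b[is_base(b)]
    if (!length(b)) return(NA_character_)
    names(sort(table(b), decreasing = TRUE))[1]
  }, character(1))
  out <- list()
  for (i in inv_rows) {
    hb <- mat[i, poly_cols]
    variant <- is_base(hb) & !is.na(consensus) & hb != consensus
    vcols <- poly_cols[variant]
    if (!length(vcols)) next
    vshared <- vcols %in% shared_cols
    r <- rle(vshared)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] < min_run) next
      first <- vcols[starts_idx[k]]
      last <- vcols[ends_idx[k]]
      prev <- if (starts_idx[k] > 1L) vcols[starts_idx[k] - 1L] else NA_integer_
      nxt <- if (ends_idx[k] < length(vcols)) vcols[ends_idx[k] + 1L] else NA_integer_
      start0 <- if (is.na(prev)) 0L else as.integer(floor((prev + first) / 2))
      end0 <- if (is.na(nxt)) L else as.integer(ceiling((last + nxt) / 2))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rownames(mat)[i], start = start0, end = end0,
        n_sites = r$lengths[k], reason = "exchange_tract",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Apply mask intervals to an alignment
#'
#' Replaces masked spans by N.  Haplotypes whose masked fraction exceeds
#' `whole_haplotype_cut` are discarded entirely (recombinant haplotypes are
#' removed from downstream analyses).  When more than half of the inverted
#' class is dropped, a warning signals that the ancestral haplotype of the
#' arrangement may be unrecoverable at this breakpoint (the situation that
#' forces excluding a breakpoint from analysis altogether).
#'
#' @param a an [inv_alignment()]
#' @param masks data.frame as returned by [detect_exchange_tracts()]
#' @param whole_haplotype_cut fraction of masked columns above which a
#'   haplotype is dropped (default 0.5)
#' @param inversion optional arrangement column name used for the
#'   excessive-masking warning
#' @return list with `alignment` (masked), `dropped` (sample ids), and
#'   `masked_fraction` (named numeric, per input sample)
#' @export
apply_masks <- function(a, masks, whole_haplotype_cut = 0.5, inversion = NULL) {
  mat <- a$mat
  L <- ncol(mat)
  frac <- stats::setNames(numeric(nrow(mat)), rownames(mat))
  if (nrow(masks)) {
    bad <- setdiff(masks$sample_id, rownames(mat))
    if (length(bad)) stop("mask refers to unknown sample(s): ", paste(bad, collapse = ", "))
    for (s in unique(masks$sample_id)) {
      covered <- logical(L)
      ms <- masks[masks$sample_id == s, , drop = FALSE]
      for (r in seq_len(nrow(ms))) {
        lo <- max(0L, ms$start[r]); hi <- min(L, ms$end[r])
        if (hi > lo) covered[(lo + 1L):hi] <- TRUE
      }
      mat[s, covered] <- "N"
      frac[s] <- mean(covered)
    }
  }
  dropped <- names(frac)[frac > whole_haplotype_cut]
  out <- a
  out$mat <- mat
  if (length(dropped)) {
    out <- subset_alignment(out, setdiff(rownames(mat), dropped))
  }
  if (!is.null(inversion) && !is.null(a$meta)) {
    arr <- get_arrangements(a, inversion)
    inv_ids <- rownames(a$mat)[arr == "inverted"]
    if (length(inv_ids) && mean(inv_ids %in% dropped) > 0.5) {
      warning("more than half of the inverted haplotypes were dropped; ",
              "exchange may be too extensive to recover the ancestral haplotype")
    }
  }
  list(alignment = out, dropped = dropped, masked_fraction = frac)
}
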