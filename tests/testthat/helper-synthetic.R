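# shared fixtures, all generated in code

# random alignment over the full 6-letter alphabet
random_alignment <- function(n = 5, L = 30, p_missing = 0.1,
                             alphabet = c("A", "C", "G", "T", "N", "-")) {
  probs <- c(rep((1 - p_missing) / 4, 4), p_missing / 2, p_missing / 2)
  mat <- matrix(sample(alphabet, n * L, replace = TRUE, prob = probs),
                nrow = n, dimnames = list(paste0("s", seq_len(n)), NULL))
  inv_alignment(mat)
}

# 0/1 haplotype matrix -> nucleotide alignment (A = ancestral, T = derived),
# padded with invariant columns so containers are never empty
hap_to_alignment <- function(hap, pad = 5L) {
  n <- nrow(hap)
  mat <- matrix("A", n, ncol(hap) + pad)
  if (ncol(hap)) mat[, seq_len(ncol(hap))][hap == 1L] <- "T"
  rownames(mat) <- paste0("s", seq_len(n))
  inv_alignment(mat)
}

# sequence pair with an exact (aligned, mismatch) count
pair_with_counts <- function(aligned, mismatches, masked = 0) {
  s1 <- rep("A", aligned + masked)
  s2 <- s1
  if (mismatches > 0) s2[seq_len(mismatches)] <- "T"
  if (masked > 0) {
    idx <- aligned + seq_len(masked)
    s2[idx] <- "N"
  }
  list(s1 = paste(s1, collapse = ""), s2 = paste(s2, collapse = ""))
}

# alignment with arrangement metadata built directly from a character matrix
alignment_with_arrangements <- function(mat, inverted_ids) {
  ids <- rownames(mat)
  meta <- data.frame(
    sample_id = ids,
    population = "RG",
    arm = "arm1",
    inv1 = ifelse(ids %in% inverted_ids, "inverted", "standard"),
    stringsAsFactors = FALSE
  )
  inv_alignment(mat, meta = meta)
}

# fraction of planted tract bases covered by detected intervals, plus the
# fraction of inverted haplotypes carrying a detection
tract_recovery <- function(planted, detected, n_inverted) {
  tot <- 0L
  hit <- 0L
  for (r in seq_len(nrow(planted))) {
    cols <- (planted$start[r] + 1L):planted$end[r]
    d <- detected[detected$sample_id == planted$sample_id[r], , drop = FALSE]
    cov <- rep(FALSE, length(cols))
    if (nrow(d)) {
      for (q in seq_len(nrow(d))) {
        cov <- cov | (cols > d$start[q] & cols <= d$end[q])
      }
    }
    tot <- tot + length(cols)
    hit <- hit + sum(cov)
  }
  list(base_recovery = if (tot) hit / tot else NA_real_,
       bases_planted = tot, bases_recovered = hit,
       flagged_fraction = length(unique(detected$sample_id)) / n_inverted)
}
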