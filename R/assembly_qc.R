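#' Compare a consensus to a trusted sequence
#'
#' Columns where both characters are unambiguous bases count as aligned;
#' aligned columns that differ are mismatches.  This is the accounting used
#' to certify consensus quality against reference-grade (Sanger) sequence.
#'
#' @param consensus,truth pre-aligned equal-length sequences (strings or
#'   character vectors)
#' @param label optional label carried into the record
#' @return data.frame of class comparison record: `label`, `aligned_bases`,
#'   `mismatches`, `divergence`
#' @export
compare_to_truth <- function(consensus, truth, label = NA_character_) {
  d <- divergence_pair(consensus, truth)
  data.frame(label = label, aligned_bases = d$aligned_bases,
             mismatches = d$mismatches, divergence = d$proportion,
             stringsAsFactors = FALSE)
}

#' Poisson upper confidence bound on an error count
#'
#' The smallest Poisson mean lambda for which observing at most `observed`
#' events has probability 1 - confidence; for zero observed errors at 95%
#' confidence this is -ln(0.05), approximately 3 errors.  Computed through
#' the gamma-Poisson identity (`qgamma(confidence, observed + 1)`).
#'
#' @param observed observed error count (>= 0)
#' @param confidence confidence level in (0, 1), default 0.95
#' @return continuous upper bound on the expected error count
#' @export
poisson_error_upper <- function(observed, confidence = 0.95) {
  if (observed < 0) stop("observed count must be >= 0")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  stats::qgamma(confidence, shape = observed + 1)
}

#' Phred-scaled quality from an error budget
#'
#' Q = -10 log10(errors / bases).  Zero errors yield the sentinel `Inf`
#' ("Q-infinity") rather than a silent cap.
#'
#' @param errors expected error count (>= 0)
#' @param bases number of bases (> 0)
#' @return Phred quality (possibly `Inf`)
#' @export
phred_quality <- function(errors, bases) {
  if (errors < 0 || bases <= 0) stop("errors must be >= 0 and bases > 0")
  if (errors == 0) return(Inf)
  -10 * log10(errors / bases)
}

#' Simple pileup consensus caller
#'
#' Emits, per position, the majority base among covering reads when the depth
#' is at least `min_depth` and the consensus quality is at least
#' `min_quality`, otherwise N.  Ties yield N.  Consensus quality is the
#' Phred-scaled majority fraction, -10 log10(1 - f); a unanimous column has
#' infinite quality and always passes.
#'
#' @param reads data.frame with columns `start` (0-based), `sequence`
#'   (read bases as a string)
#' @param region_length length of the region being called
#' @param min_depth minimum read depth (default 3)
#' @param min_quality minimum consensus quality (default 50)
#' @return consensus sequence string of length `region_length`
#' @export
pileup_consensus <- function(reads, region_length, min_depth = 3L, min_quality = 50) {
  counts <- matrix(0L, nrow = 4, ncol = region_length,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (r in seq_len(nrow(reads))) {
    bases <- strsplit(toupper(reads$sequence[r]), "")[[1]]
    pos <- reads$start[r] + seq_along(bases)  # 1-based columns
    ok <- pos >= 1 & pos <= region_length & bases %in% rownames(counts)
    for (i in which(ok)) {
      counts[bases[i], pos[i]] <- counts[bases[i], pos[i]] + 1L
    }
  }
  depth <- colSums(counts)
  out <- rep("N", region_length)
  for (j in which(depth >= min_depth)) {
    cj <- counts[, j]
    top <- max(cj)
    if (sum(cj == top) > 1L) next  # tie
    f <- top / depth[j]
    q <- if (f == 1) Inf else -10 * log10(1 - f)
    if (q >= min_quality) out[j] <- rownames(counts)[which.max(cj)]
  }
  paste(out, collapse = "")
}

#' Simulate a read set over a truth sequence
#'
#' Uniform-start fixed-length reads with optional per-base substitution
#' error; the fixture format used by the depth-titration harness.
#'
#' @param truth truth sequence (string)
#' @param depth target mean coverage
#' @param read_length read length in bp
#' @param error_rate per-base substitution error probability
#' @return data.frame with `start` (0-based) and `sequence`
#' @export
simulate_reads <- function(truth, depth = 20, read_length = 100, error_rate = 0) {
  L <- nchar(truth)
  n_reads <- ceiling(depth * L / read_length)
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
  tv <- strsplit(toupper(truth), "")[[1]]
  seqs <- vapply(starts, function(s) {
    b <- tv[(s + 1):(s + read_length)]
    if (error_rate > 0) {
      err <- stats::runif(read_length) < error_rate
      if (any(err)) {
        b[err] <- vapply(b[err], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1)
        }, character(1))
      }
    }
    paste(b, collapse = "")
  }, character(1))
  data.frame(start = starts, sequence = seqs, stringsAsFactors = FALSE)
}

#' Depth-titration bootstrap of consensus accuracy
#'
#' Randomly discards reads, rebuilds the consensus at each retained fraction,
#' and records divergence to a reference and callable coverage, both
#' normalized by the values obtained from the truth sequence — an unbiased
#' caller keeps normalized divergence near 1 even at low depth.
#'
#' @param reads data.frame of reads (see [simulate_reads()])
#' @param truth truth sequence the reads derive from
#' @param reference reference sequence divergence is measured against
#' @param fractions retained-read fractions (default 0.1 to 0.9 by 0.1)
#' @param reps bootstrap replicates per fraction (default 100)
#' @param min_depth,min_quality consensus-calling thresholds, see
#'   [pileup_consensus()]
#' @return data.frame with columns `fraction`, `rep`, `divergence_ratio`,
#'   `coverage_ratio`
#' @export
depth_titration <- function(reads, truth, reference,
                            fractions = seq(0.1, 0.9, by = 0.1), reps = 100,
                            min_depth = 3L, min_quality = 50) {
  L <- nchar(truth)
  true_div <- divergence_pair(truth, reference)$proportion
  full_cov <- sum(strsplit(pileup_consensus(reads, L, min_depth, min_quality),
                           "")[[1]] != "N")
  out <- vector("list", length(fractions) * reps)
  k <- 0L
  for (f in fractions) {
    n_keep <- max(1L, round(f * nrow(reads)))
    for (r in seq_len(reps)) {
      keep <- sample.int(nrow(reads), n_keep)
      cons <- pileup_consensus(reads[keep, , drop = FALSE], L, min_depth, min_quality)
      d <- divergence_pair(cons, reference)
      cov <- sum(strsplit(cons, "")[[1]] != "N")
      k <- k + 1L
      out[[k]] <- data.frame(
        fraction = f, rep = r,
        divergence_ratio = if (true_div > 0) d$proportion / true_div else NA_real_,
        coverage_ratio = if (full_cov > 0) cov / full_cov else NA_real_
      )
    }
  }
  do.call(rbind, out)
}
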