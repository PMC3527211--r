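#' @useDynLib invgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
ARRANGEMENTS <- c("inverted", "standard", "unknown")

#' Construct a haplotype alignment
#'
#' The central container for breakpoint-proximal sequence data: a matrix of
#' aligned haplotypes over the six-letter alphabet \{A,C,G,T,N,-\}, with
#' genomic coordinates and (optionally) per-sample metadata.  All statistics
#' in the package consume this class.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix of single characters (samples in rows).
#' @param sample_ids unique sample identifiers, one per sequence.
#' @param region list with elements `arm`, `start`, `end` (0-based,
#'   half-open reference coordinates).  Defaults to an anonymous region
#'   spanning the alignment.
#' @param meta optional `data.frame` of per-sample metadata with a
#'   `sample_id` column (see [read_sample_meta()]).
#' @return an object of class `inv_alignment`: a list with elements `mat`
#'   (character matrix), `region`, `meta`, and `col_map` (map from current
#'   columns back to original alignment columns).
#' @export
inv_alignment <- function(seqs, sample_ids = NULL, region = NULL, meta = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(sample_ids)) sample_ids <- rownames(mat)
  } else {
    if (is.null(sample_ids)) sample_ids <- names(seqs)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (ncol(mat) < 1L) stop("alignment must have length >= 1")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  rownames(mat) <- sample_ids
  mat <- normalize_alignment_matrix(mat)
  if (is.null(region)) region <- list(arm = NA_character_, start = 0L, end = ncol(mat))
  if (!is.null(meta)) {
    missing <- setdiff(sample_ids, meta$sample_id)
    if (length(missing)) {
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    }
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(
    list(mat = mat, region = region, meta = meta, col_map = seq_len(ncol(mat))),
    class = "inv_alignment"
  )
}

# uppercase, map IUPAC ambiguity codes (residual heterozygosity) to N
normalize_alignment_matrix <- function(mat) {
  mat[] <- toupper(mat)
  bad <- !(mat %in% ALN_ALPHABET)
  if (any(bad)) {
    codes <- unique(mat[bad])
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U", ".")
    if (!all(codes %in% iupac)) {
      stop("alphabet error: illegal characters in alignment: ",
           paste(setdiff(codes, iupac), collapse = ", "))
    }
    warning(sum(bad), " ambiguity-coded site(s) (",
            paste(codes, collapse = ","), ") converted to N")
    mat[bad] <- "N"
  }
  mat
}

#' @export
print.inv_alignment <- function(x, ...) {
  cat(sprintf("inv_alignment: %d haplotypes x %d columns", nrow(x$mat), ncol(x$mat)))
  if (!is.na(x$region$arm)) {
    cat(sprintf(" [%s:%d-%d]", x$region$arm, x$region$start, x$region$end))
  }
  cat("\n")
  if (!is.null(x$meta)) cat("  metadata columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / alignment length
#' @param a an `inv_alignment`
#' @return integer count
#' @export
n_haplotypes <- function(a) nrow(a$mat)

#' @rdname n_haplotypes
#' @export
alignment_length <- function(a) ncol(a$mat)

#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment.  Sequences are uppercased; IUPAC
#' ambiguity codes other than N (residual heterozygosity) are converted to N
#' with a warning, matching the policy of masking putatively heterozygous
#' sites before analysis.
#'
#' @param path FASTA file path.
#' @param arm,start optional reference coordinates of the aligned region
#'   (0-based start).
#' @param meta optional metadata `data.frame` (see [read_sample_meta()]).
#' @return an [inv_alignment()]
#' @export
read_fasta_alignment <- function(path, arm = NA_character_, start = 0L, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L) stop("FASTA contains no records")
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment-shape error: FASTA records have unequal lengths")
  }
  inv_alignment(seqs, sample_ids = ids,
                region = list(arm = arm, start = as.integer(start),
                              end = as.integer(start) + unique(lens)),
                meta = meta)
}

#' Write an alignment to FASTA
#' @param a an `inv_alignment`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fasta_alignment <- function(a, path) {
  seqs <- apply(a$mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(a$mat)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Tab-separated with a header; requires columns `sample_id`, `population`,
#' `arm`; every additional column is interpreted as an inversion whose values
#' must be one of `inverted`, `standard`, `unknown`.
#'
#' @param path TSV file path
#' @return `data.frame`
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "arm")
  if (!all(req %in% names(meta))) {
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  }
  inv_cols <- setdiff(names(meta), req)
  for (cc in inv_cols) {
    bad <- setdiff(unique(meta[[cc]]), ARRANGEMENTS)
    if (length(bad)) {
      stop("arrangement labels in column '", cc, "' must be one of ",
           paste(ARRANGEMENTS, collapse = "/"), "; found: ",
           paste(bad, collapse = ", "))
    }
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta
}

#' Read genomic intervals (BED3+name)
#'
#' Thin wrapper over `rtracklayer::import`; coordinates are returned as a
#' `GRanges` (rtracklayer converts BED's 0-based half-open records to the
#' 1-based closed convention GRanges uses; this package's numeric interfaces
#' are 0-based half-open and conversion helpers are provided).
#'
#' @param path BED file path
#' @return `GRanges` with a `name` metadata column when present
#' @export
read_intervals <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Convert a 0-based half-open interval table to GRanges (and back)
#'
#' @param df data.frame with columns `arm`, `start`, `end` and optionally
#'   `name` (0-based half-open).
#' @return `GRanges`
#' @export
intervals_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$arm,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(df$name)) gr$name <- df$name
  gr
}

#' @rdname intervals_to_granges
#' @param gr a `GRanges`
#' @export
granges_to_intervals <- function(gr) {
  data.frame(
    arm = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Remove all columns containing gaps or missing data
#'
#' Complete-deletion filtering: every column containing any `-` or `N` in any
#' retained sample is removed before computing summary statistics.  The
#' returned alignment's `col_map` maps surviving columns to the original
#' coordinates.
#'
#' @param a an `inv_alignment`
#' @return filtered `inv_alignment` (possibly of length 0, with a warning)
#' @export
complete_deletion <- function(a) {
  keep <- colSums(a$mat == "N" | a$mat == "-") == 0L
  if (!any(keep)) warning("complete deletion removed every column")
  out <- a
  out$mat <- a$mat[, keep, drop = FALSE]
  out$col_map <- a$col_map[keep]
  out
}

#' Subset an alignment by sample and/or column range
#'
#' @param a an `inv_alignment`
#' @param samples character vector of sample ids to retain (order preserved);
#'   `NULL` keeps all.
#' @param interval optional `c(start, end)` column range, 0-based half-open
#'   in current alignment columns.
#' @return `inv_alignment`
#' @export
subset_alignment <- function(a, samples = NULL, interval = NULL) {
  out <- a
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(a$mat))
    if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    out$mat <- out$mat[samples, , drop = FALSE]
    if (!is.null(out$meta)) {
      out$meta <- out$meta[match(samples, out$meta$sample_id), , drop = FALSE]
      rownames(out$meta) <- NULL
    }
  }
  if (!is.null(interval)) {
    if (interval[1] < 0 || interval[2] > ncol(out$mat) || interval[1] >= interval[2]) {
      stop("interval out of range")
    }
    cols <- (interval[1] + 1L):interval[2]
    out$mat <- out$mat[, cols, drop = FALSE]
    out$col_map <- out$col_map[cols]
  }
  out
}

#' Flag chromosome arms with long tracks of residual heterozygosity
#'
#' Assemblies from incompletely inbred lines show long runs of windows with
#' elevated heterozygous calls; such (sample, arm) combinations are excluded
#' wholesale.  A combination is flagged when at least `run_threshold`
#' consecutive windows exceed `het_fraction_cut`.
#'
#' @param het data.frame with columns `sample`, `arm`, `window` (1-based
#'   index along the arm; windows tile the arm, default width 500 kb), and
#'   `het_fraction`.
#' @param run_threshold minimum number of consecutive elevated windows
#'   (default 3).
#' @param het_fraction_cut heterozygosity fraction above which a window is
#'   considered elevated (default 0.005).
#' @return data.frame of excluded (sample, arm) pairs with the longest
#'   elevated run observed.
#' @export
mask_het_arms <- function(het, run_threshold = 3L, het_fraction_cut = 0.005) {
  stopifnot(all(c("sample", "arm", "window", "het_fraction") %in% names(het)))
  out <- list()
  for (key in split(het, list(het$sample, het$arm), drop = TRUE)) {
    key <- key[order(key$window), ]
    elevated <- key$het_fraction > het_fraction_cut
    run <- max_run_length(elevated)
    if (run >= run_threshold) {
      out[[length(out) + 1L]] <- data.frame(
        sample = key$sample[1], arm = key$arm[1], longest_run = run,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(), arm = character(),
                      longest_run = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

max_run_length <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}
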