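#' Mean divergence from inverted haplotypes to a reference group
#'
#' Average, over all inverted x reference pairs, of the per-site mismatch
#' proportion.  Columns containing gaps or N in the compared set are removed
#' first (complete deletion within the comparison) so missing data cannot
#' masquerade as divergence.
#'
#' @param a an [inv_alignment()]
#' @param inv_ids inverted haplotype sample ids
#' @param group_ids reference (standard) haplotype sample ids
#' @return mean per-site divergence
#' @export
mean_divergence_to_group <- function(a, inv_ids, group_ids) {
  if (!length(inv_ids) || !length(group_ids)) stop("groups must be non-empty")
  sub <- complete_deletion(subset_alignment(a, unique(c(inv_ids, group_ids))))
  if (!ncol(sub$mat)) stop("no comparable columns after complete deletion")
  mean(vapply(inv_ids, function(i) {
    vapply(group_ids, function(g) {
      divergence_pair(sub$mat[i, ], sub$mat[g, ])$proportion
    }, numeric(1))
  }, numeric(length(group_ids))))
}

#' Nearest standard haplotype to the inverted class
#'
#' Finds the standard haplotype with minimal divergence to any inverted
#' haplotype.  Ties within rounding are all reported; when tied neighbors
#' come from different populations the tie escalates the origin call to
#' Ambiguous.
#'
#' @param a an [inv_alignment()] whose `meta` has a `population` column
#' @param inv_ids inverted haplotype sample ids
#' @param standard_ids candidate standard haplotype ids
#' @return data.frame of the minimal-divergence neighbor(s): `sample_id`,
#'   `population`, `divergence`
#' @export
nearest_neighbor <- function(a, inv_ids, standard_ids) {
  if (!length(standard_ids)) stop("need at least one standard haplotype")
  sub <- complete_deletion(subset_alignment(a, unique(c(inv_ids, standard_ids))))
  if (!ncol(sub$mat)) stop("no comparable columns after complete deletion")
  div <- vapply(standard_ids, function(g) {
    min(vapply(inv_ids, function(i) {
      divergence_pair(sub$mat[i, ], sub$mat[g, ])$proportion
    }, numeric(1)))
  }, numeric(1))
  best <- min(div)
  hit <- standard_ids[div <= best + 1e-12]
  pop <- a$meta$population[match(hit, a$meta$sample_id)]
  data.frame(sample_id = hit, population = pop, divergence = div[hit],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify the geographic origin of an inversion at one breakpoint
#'
#' The two-condition rule: an inversion is judged Cosmopolitan only when (i)
#' the nearest standard neighbor is a cosmopolitan (French) sequence and (ii)
#' the mean divergence to the cosmopolitan standards is smaller than the mean
#' divergence to the African standards.  African haplotypes satisfy neither
#' condition under the out-of-Africa bottleneck model; a nearest-neighbor tie
#' across populations yields Ambiguous.
#'
#' @param a an [inv_alignment()] with `population` metadata
#' @param inv_ids inverted haplotype ids
#' @param cosmopolitan_ids standard haplotypes from the bottlenecked
#'   (cosmopolitan, e.g. French) population
#' @param african_ids standard haplotypes from the diverse (African)
#'   population, pre-masked for admixture by the caller
#' @return list of class `origin_report`: `call` (African / Cosmopolitan /
#'   Ambiguous), `mean_div_cosmopolitan`, `mean_div_african`,
#'   `nearest` (data.frame)
#' @export
classify_origin_breakpoint <- function(a, inv_ids, cosmopolitan_ids, african_ids) {
  if (!length(cosmopolitan_ids) || !length(african_ids)) {
    stop("both reference groups must be non-empty")
  }
  d_cos <- mean_divergence_to_group(a, inv_ids, cosmopolitan_ids)
  d_afr <- mean_divergence_to_group(a, inv_ids, african_ids)
  nn <- nearest_neighbor(a, inv_ids, c(cosmopolitan_ids, african_ids))
  nn_pops <- unique(nn$population)
  cos_pops <- unique(a$meta$population[match(cosmopolitan_ids, a$meta$sample_id)])
  call <- if (length(nn_pops) > 1L &&
              any(nn_pops %in% cos_pops) && any(!nn_pops %in% cos_pops)) {
    "Ambiguous"
  } else if (all(nn_pops %in% cos_pops) && d_cos < d_afr) {
    "Cosmopolitan"
  } else {
    "African"
  }
  structure(list(call = call, mean_div_cosmopolitan = d_cos,
                 mean_div_african = d_afr, nearest = nn),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat(sprintf("origin call: %s (mean div cosmopolitan %.5f, African %.5f; nearest: %s [%s])\n",
              x$call, x$mean_div_cosmopolitan, x$mean_div_african,
              paste(x$nearest$sample_id, collapse = ","),
              paste(unique(x$nearest$population), collapse = ",")))
  invisible(x)
}

#' Combine per-breakpoint origin calls for one inversion
#'
#' Breakpoint-level calls are combined by unanimity: the inversion-level call
#' is made only when every analyzed breakpoint agrees, otherwise Ambiguous.
#'
#' @param reports list of `origin_report` objects (one per breakpoint)
#' @return list with the combined `call` and the per-breakpoint `reports`
#' @export
classify_origin <- function(reports) {
  if (inherits(reports, "origin_report")) reports <- list(reports)
  calls <- vapply(reports, function(r) r$call, character(1))
  call <- if (length(unique(calls)) == 1L && calls[1] != "Ambiguous") {
    calls[1]
  } else {
    "Ambiguous"
  }
  list(call = call, reports = reports)
}
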