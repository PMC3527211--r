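#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the data structure the analyses assume: a diverse
#' African standard sample (per-site theta 0.01, typical of African
#' D. melanogaster), a bottlenecked cosmopolitan sample sharing recent
#' ancestry with it, and an inverted clade nested at a depth corresponding to
#' the requested age under the divergence calibration (d = 0.06 to the sister
#' species over 3e7 generations, 10 generations per year).  Exchange tracts,
#' indels, and missing data are injected last, with ground truth recorded.
#'
#' @param age_years true inversion age in years
#' @param origin `"African"` or `"Cosmopolitan"`: which population the
#'   captured haplotype is drawn from
#' @param L region length in bp
#' @param theta_site per-site population-scaled mutation rate
#' @param n_inverted,n_standard_african,n_standard_cosmopolitan sample sizes
#' @param bottleneck cosmopolitan diversity as a fraction of African
#' @param bottleneck_age_years age of the out-of-Africa founding event; the
#'   cosmopolitan standards coalesce within this depth (default 15000)
#' @param d,t_gen,gens_per_year mutation-rate calibration (see
#'   [expected_theta()])
#' @param exchange_rate per-inverted-haplotype probability of carrying one
#'   exchange tract
#' @param exchange_tract_mean mean tract length in bp
#' @param indel_rate expected indels per haplotype
#' @param indel_mean_len mean indel length in bp
#' @param missing_fraction per-base probability of missing data (N)
#' @param arm_lengths named vector of arm lengths for annotation
#' @param gene_density target genic fraction of each arm
#' @param gene_mean_len mean gene length in bp
#' @param n_breakpoints breakpoints to place per arm
#' @param breakpoint_mode `"uniform"` or `"avoid"` (genes)
#' @param true_K true female proportion in experimental crosses
#' @param n_experimental,n_control numbers of crosses
#' @param f1_males_per_cross F1 males scored per cross
#' @param mean_brood mean progeny per F1 male
#' @return named list of class `scenario_config`
#' @export
scenario_config <- function(age_years = 5000, origin = c("African", "Cosmopolitan"),
                            L = 5000L, theta_site = 0.01,
                            n_inverted = 8L, n_standard_african = 20L,
                            n_standard_cosmopolitan = 10L, bottleneck = 0.3,
                            bottleneck_age_years = 15000,
                            d = 0.06, t_gen = 3e7, gens_per_year = 10,
                            exchange_rate = 0.3, exchange_tract_mean = 1500,
                            indel_rate = 1, indel_mean_len = 8,
                            missing_fraction = 0.005,
                            arm_lengths = c(arm1 = 2e6), gene_density = 0.3,
                            gene_mean_len = 1000, n_breakpoints = 16L,
                            breakpoint_mode = c("uniform", "avoid"),
                            true_K = 0.541, n_experimental = 11L, n_control = 9L,
                            f1_males_per_cross = 5L, mean_brood = 120) {
  cfg <- list(
    age_years = age_years, origin = match.arg(origin), L = as.integer(L),
    theta_site = theta_site, n_inverted = as.integer(n_inverted),
    n_standard_african = as.integer(n_standard_african),
    n_standard_cosmopolitan = as.integer(n_standard_cosmopolitan),
    bottleneck = bottleneck, bottleneck_age_years = bottleneck_age_years,
    d = d, t_gen = t_gen,
    gens_per_year = gens_per_year, exchange_rate = exchange_rate,
    exchange_tract_mean = exchange_tract_mean, indel_rate = indel_rate,
    indel_mean_len = indel_mean_len, missing_fraction = missing_fraction,
    arm_lengths = arm_lengths, gene_density = gene_density,
    gene_mean_len = gene_mean_len, n_breakpoints = as.integer(n_breakpoints),
    breakpoint_mode = match.arg(breakpoint_mode), true_K = true_K,
    n_experimental = as.integer(n_experimental), n_control = as.integer(n_control),
    f1_males_per_cross = as.integer(f1_males_per_cross), mean_brood = mean_brood
  )
  stopifnot(cfg$age_years >= 0, cfg$theta_site >= 0,
            cfg$bottleneck > 0, cfg$bottleneck <= 1,
            cfg$exchange_rate >= 0, cfg$exchange_rate <= 1,
            cfg$missing_fraction >= 0, cfg$missing_fraction <= 1,
            cfg$true_K > 0, cfg$true_K < 1)
  class(cfg) <- "scenario_config"
  cfg
}

# scaled depth (4N0 units) of a clade of the given age in years
age_to_scaled_depth <- function(cfg, age_years = cfg$age_years) {
  mu_region_gen <- cfg$d / (2 * cfg$t_gen) * cfg$L
  theta_region <- cfg$theta_site * cfg$L
  age_years * cfg$gens_per_year * mu_region_gen / theta_region
}

# growth rate making the expected clade T_MRCA match the requested depth, so
# the inverted genealogy is star-like the way the analysis model assumes
# (approximation E[T_MRCA | alpha] ~ log1p(alpha * E0) / alpha, E0 = 1 - 1/n)
clade_growth_rate <- function(n, depth) {
  e0 <- 1 - 1 / n
  if (depth <= 0 || depth >= e0) return(0)
  stats::uniroot(function(a) log1p(a * e0) / a - depth,
                 lower = 1e-8, upper = 1e12, tol = 1e-9)$root
}

# nucleotide matrix from a binary haplotype matrix: each segregating site is
# assigned a distinct column of a random reference background
seed_background <- function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE)

alt_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
}

#' Generate a synthetic breakpoint-region dataset
#'
#' Standard African haplotypes come from a neutral coalescent at
#' theta_site * L; cosmopolitan standards form a shallow clade (rescaled
#' theta) descending from one African haplotype; the inverted clade descends
#' from a haplotype of the configured origin population at a scaled depth
#' matching the requested age, so expected inverted-standard net divergence
#' is 2 mu T.  Exchange tracts are then copied from random African standard
#' haplotypes into inverted ones, and indels plus missing data injected last.
#'
#' @param cfg a [scenario_config()]
#' @return list with `alignment` (an [inv_alignment()] with metadata),
#'   `ledger` (ground truth: true age, origin, planted tracts, clade depth)
#' @export
generate_breakpoint_region <- function(cfg) {
  L <- cfg$L
  theta_region <- cfg$theta_site * L
  n_afr <- cfg$n_standard_african
  n_cos <- cfg$n_standard_cosmopolitan
  n_inv <- cfg$n_inverted
  # base genealogy: African standards + cosmopolitan founder lineage
  base <- drop_mutations(sample_genealogy(n_afr + 1L), theta_region)
  ref <- seed_background(L)
  free_cols <- sample.int(L)  # disjoint column assignment across mutation sets
  take_cols <- function(k) {
    if (k > length(free_cols)) stop("region too short for the mutation load")
    out <- free_cols[seq_len(k)]
    free_cols <<- free_cols[-seq_len(k)]
    out
  }
  mat <- matrix(rep(ref, each = n_afr + 1L), nrow = n_afr + 1L)
  s_base <- ncol(base$haplotypes)
  if (s_base > 0) {
    cols <- take_cols(s_base)
    alts <- alt_base(ref[cols])
    for (j in seq_len(s_base)) {
      mat[base$haplotypes[, j] == 1L, cols[j]] <- alts[j]
    }
  }
  afr_mat <- mat[seq_len(n_afr), , drop = FALSE]
  founder <- mat[n_afr + 1L, ]
  # cosmopolitan clade: bottlenecked diversity, shared recent ancestry
  add_clade <- function(founder_seq, n, theta, depth = NULL, alpha = 0) {
    g <- sample_genealogy(n, alpha)
    if (!is.null(depth)) {
      scale <- if (g$t_mrca > 0) depth / g$t_mrca else 0
      g$t_mrca <- depth
      g$t_total <- g$t_total * scale
      g$branches$length <- g$branches$length * scale
    }
    mut <- drop_mutations(g, theta)
    cl <- matrix(rep(founder_seq, each = n), nrow = n)
    s <- ncol(mut$haplotypes)
    if (s > 0) {
      cols <- take_cols(s)
      alts <- alt_base(founder_seq[cols])
      for (j in seq_len(s)) {
        cl[mut$haplotypes[, j] == 1L, cols[j]] <- alts[j]
      }
    }
    list(mat = cl, t_mrca = g$t_mrca)
  }
  # the bottleneck imposes shared recent ancestry (clade depth = age of the
  # out-of-Africa event) on top of the rescaled diversity; the founder lineage
  # itself accrues mutations since the split, so cosmopolitan haplotypes are
  # never sequence-identical to their African sister lineage
  depth_cos <- age_to_scaled_depth(cfg, cfg$bottleneck_age_years)
  n_split <- stats::rpois(1, theta_region * depth_cos)
  if (n_split > 0) {
    cols <- take_cols(n_split)
    founder[cols] <- alt_base(founder[cols])
  }
  cos <- add_clade(founder, n_cos, theta_region * cfg$bottleneck,
                   depth = depth_cos, alpha = clade_growth_rate(n_cos, depth_cos))
  # inversion ancestor: drawn from the origin population, diverged age ago
  depth <- age_to_scaled_depth(cfg)
  if (cfg$origin == "Cosmopolitan" && cfg$age_years > cfg$bottleneck_age_years) {
    stop("infeasible configuration: a cosmopolitan-origin inversion cannot ",
         "predate the founding bottleneck")
  }
  source_seq <- if (cfg$origin == "African") {
    afr_mat[sample.int(n_afr, 1L), ]
  } else {
    cos$mat[sample.int(n_cos, 1L), ]
  }
  ancestor <- source_seq
  n_branch <- stats::rpois(1, theta_region * depth)  # source-lineage back-path
  if (n_branch > 0) {
    cols <- take_cols(n_branch)
    ancestor[cols] <- alt_base(ancestor[cols])
  }
  inv <- add_clade(ancestor, n_inv, theta_region, depth = depth,
                   alpha = clade_growth_rate(n_inv, depth))
  inv_mat <- inv$mat
  ids <- c(paste0("inv", seq_len(n_inv)),
           paste0("afr", seq_len(n_afr)),
           paste0("cos", seq_len(n_cos)))
  full <- rbind(inv_mat, afr_mat, cos$mat)
  rownames(full) <- ids
  # exchange tracts: copy a segment of a random African standard haplotype.
  # A copied segment that differs from the recipient at fewer than 3 sites is
  # not an observable event (no multi-site signature exists in the data), so
  # such draws are re-drawn, capped; the ledger records only realized tracts.
  tracts <- list()
  for (i in seq_len(n_inv)) {
    if (stats::runif(1) >= cfg$exchange_rate) next
    for (try in seq_len(20L)) {
      tlen <- min(L, max(100L, round(stats::rexp(1, 1 / cfg$exchange_tract_mean))))
      start0 <- sample.int(L - tlen + 1L, 1L) - 1L
      donor <- sample.int(n_afr, 1L)
      seg <- (start0 + 1L):(start0 + tlen)
      n_diff <- sum(afr_mat[donor, seg] != full[i, seg])
      if (n_diff >= 3L) break
    }
    if (n_diff < 3L) next  # no identifiable planting found; skip
    pre_plant <- full[i, seg]
    full[i, seg] <- afr_mat[donor, seg]
    tracts[[length(tracts) + 1L]] <- list(
      sample_id = ids[i], row = i, start = start0, end = start0 + tlen,
      donor = paste0("afr", donor), n_diff = n_diff, pre_plant = pre_plant
    )
  }
  # indels as contiguous gap runs, then missing data
  n_total <- nrow(full)
  for (i in seq_len(n_total)) {
    k <- stats::rpois(1, cfg$indel_rate)
    for (z in seq_len(k)) {
      ilen <- 1L + stats::rpois(1, max(0, cfg$indel_mean_len - 1))
      s0 <- sample.int(max(1L, L - ilen + 1L), 1L) - 1L
      full[i, (s0 + 1L):min(L, s0 + ilen)] <- "-"
    }
    nmiss <- stats::rbinom(1, L, cfg$missing_fraction)
    if (nmiss > 0) full[i, sample.int(L, nmiss)] <- "N"
  }
  # the ledger reports how many of each tract's diagnostic sites survived the
  # indel/missing injection (n_visible); tracts with n_visible below the
  # detection floor exist in the data but are not observable events
  base_chr <- c("A", "C", "G", "T")
  tracts <- if (length(tracts)) {
    do.call(rbind, lapply(tracts, function(tr) {
      seg <- (tr$start + 1L):tr$end
      now <- full[tr$row, seg]
      vis <- sum(now %in% base_chr & tr$pre_plant %in% base_chr & now != tr$pre_plant)
      data.frame(sample_id = tr$sample_id, start = tr$start, end = tr$end,
                 donor = tr$donor, n_diff = tr$n_diff, n_visible = vis,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(sample_id = character(), start = integer(), end = integer(),
               donor = character(), n_diff = integer(), n_visible = integer(),
               stringsAsFactors = FALSE)
  }
  meta <- data.frame(
    sample_id = ids,
    population = c(rep("RG", n_inv), rep("RG", n_afr), rep("FR", n_cos)),
    arm = "arm1",
    inv1 = c(rep("inverted", n_inv), rep("standard", n_afr + n_cos)),
    stringsAsFactors = FALSE
  )
  aln <- inv_alignment(full, region = list(arm = "arm1", start = 0L, end = L),
                       meta = meta)
  ledger <- list(
    age_years = cfg$age_years, origin = cfg$origin,
    clade_depth_scaled = depth, clade_t_mrca = inv$t_mrca,
    theta_region = theta_region,
    mu_region_per_year = mu_region_per_year(cfg$L, cfg$d, cfg$t_gen, cfg$gens_per_year),
    tracts = tracts
  )
  list(alignment = aln, ledger = ledger)
}

#' Generate a synthetic gene annotation and breakpoint set
#'
#' Genes are laid down as alternating intergenic/genic segments with
#' gamma-distributed lengths tuned to the configured genic fraction;
#' breakpoints are placed uniformly, or rejected out of genes in `"avoid"`
#' mode.
#'
#' @param cfg a [scenario_config()]
#' @return list with `genes` and `breakpoints` (0-based half-open interval
#'   data.frames), `arm_lengths`, and a `ledger` of placement mode
#' @export
generate_annotation <- function(cfg) {
  genes <- list()
  bps <- list()
  for (arm in names(cfg$arm_lengths)) {
    alen <- cfg$arm_lengths[[arm]]
    if (cfg$gene_density >= 1) {
      genes[[arm]] <- data.frame(arm = arm, start = 0, end = alen,
                                 name = paste0(arm, "_g1"),
                                 stringsAsFactors = FALSE)
    } else {
      gap_mean <- cfg$gene_mean_len * (1 - cfg$gene_density) / cfg$gene_density
      pos <- 0
      gs <- list()
      k <- 0L
      shape <- 4  # moderate length variance keeps realized density close to target
      while (pos < alen) {
        pos <- pos + stats::rgamma(1, shape, rate = shape / gap_mean)
        glen <- stats::rgamma(1, shape, rate = shape / cfg$gene_mean_len)
        if (pos >= alen) break
        k <- k + 1L
        gs[[k]] <- data.frame(arm = arm, start = floor(pos),
                              end = min(alen, ceiling(pos + glen)),
                              name = sprintf("%s_g%d", arm, k),
                              stringsAsFactors = FALSE)
        pos <- pos + glen
      }
      genes[[arm]] <- if (k) do.call(rbind, gs) else
        data.frame(arm = character(), start = numeric(), end = numeric(),
                   name = character(), stringsAsFactors = FALSE)
    }
    draw_bp <- function() floor(stats::runif(1, 0, alen))
    pts <- numeric(cfg$n_breakpoints)
    for (b in seq_len(cfg$n_breakpoints)) {
      p <- draw_bp()
      if (cfg$breakpoint_mode == "avoid" && nrow(genes[[arm]])) {
        while (any(p >= genes[[arm]]$start & p < genes[[arm]]$end)) p <- draw_bp()
      }
      pts[b] <- p
    }
    bps[[arm]] <- data.frame(arm = arm, pos = pts,
                             name = sprintf("%s_bp%d", arm, seq_len(cfg$n_breakpoints)),
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  bps <- do.call(rbind, bps)
  rownames(bps) <- NULL
  list(genes = genes, breakpoints = bps, arm_lengths = cfg$arm_lengths,
       ledger = list(mode = cfg$breakpoint_mode,
                     genic_fraction = sum(genes$end - genes$start) / sum(cfg$arm_lengths)))
}

#' Generate synthetic cross progeny counts
#'
#' Experimental crosses draw female counts Binomial(brood, true_K) with
#' Poisson brood sizes per F1 male; control crosses use K = 1/2.
#'
#' @param cfg a [scenario_config()]
#' @return list with `records` (data.frame in the cross-table schema) and
#'   `ledger` (true K per role)
#' @export
generate_cross_counts <- function(cfg) {
  make <- function(n, K, role, prefix) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      broods <- stats::rpois(cfg$f1_males_per_cross, cfg$mean_brood)
      total <- sum(broods)
      females <- stats::rbinom(1, total, K)
      out[[i]] <- data.frame(
        x_line = sprintf("%sX%d", prefix, i), y_line = sprintf("%sY%d", prefix, i),
        f1_males = cfg$f1_males_per_cross, females = females,
        males = total - females, eggs = NA_real_, role = role,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }
  records <- rbind(make(cfg$n_experimental, cfg$true_K, "experimental", "E"),
                   make(cfg$n_control, 0.5, "control", "C"))
  list(records = records,
       ledger = list(true_K_experimental = cfg$true_K, true_K_control = 0.5))
}

#' Generate a complete synthetic scenario
#'
#' Bundles [generate_breakpoint_region()], [generate_annotation()], and
#' [generate_cross_counts()] and, when `dir` is given, writes the standard
#' file formats (FASTA alignment, metadata TSV, gene/breakpoint BED, cross
#' TSV, truth-ledger JSON when jsonlite is available).
#'
#' @param cfg a [scenario_config()]
#' @param dir optional output directory
#' @return list with `region`, `annotation`, `crosses` and the file paths
#'   written (if any)
#' @export
generate_scenario <- function(cfg = scenario_config(), dir = NULL) {
  region <- generate_breakpoint_region(cfg)
  annotation <- generate_annotation(cfg)
  crosses <- generate_cross_counts(cfg)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      fasta = file.path(dir, "breakpoint_region.fasta"),
      meta = file.path(dir, "samples.tsv"),
      genes = file.path(dir, "genes.bed"),
      breakpoints = file.path(dir, "breakpoints.bed"),
      crosses = file.path(dir, "crosses.tsv"),
      ledger = file.path(dir, "truth.json")
    )
    write_fasta_alignment(region$alignment, files[["fasta"]])
    utils::write.table(region$alignment$meta, files[["meta"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed <- function(df, path, point = FALSE) {
      bed <- if (point) {
        data.frame(df$arm, df$pos, df$pos + 1L, df$name)
      } else {
        data.frame(df$arm, df$start, df$end, df$name)
      }
      utils::write.table(bed, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    write_bed(annotation$genes, files[["genes"]])
    write_bed(annotation$breakpoints, files[["breakpoints"]], point = TRUE)
    utils::write.table(crosses$records, files[["crosses"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      ledger <- list(region = region$ledger, annotation = annotation$ledger,
                     crosses = crosses$ledger)
      jsonlite::write_json(ledger, files[["ledger"]], auto_unbox = TRUE,
                           digits = NA)
    } else {
      files <- files[names(files) != "ledger"]
    }
  }
  list(region = region, annotation = annotation, crosses = crosses,
       files = files)
}
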