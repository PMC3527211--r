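#' Expected theta of an inverted sub-population
#'
#' The prior scale for the ABC run.  The regional mutation rate per
#' generation is derived from interspecific divergence, mu_region =
#' (d / (2 t_gen)) * L (divergence accrues along two lineages), and the
#' current effective size of the inverted class is Ne * f, giving
#' theta_hat = 4 (Ne f) mu_region = 2 Ne f d L / t_gen.
#'
#' @param L aligned region length in bp
#' @param d per-site divergence between the focal species and its sister
#'   (here D. melanogaster vs D. simulans)
#' @param t_gen interspecific divergence time in generations (default 3e7)
#' @param Ne effective population size (default 1e6)
#' @param f inversion frequency in the sample, in (0, 1]
#' @return theta_hat, the expected population-scaled mutation rate of the
#'   inverted class per region
#' @export
expected_theta <- function(L, d, t_gen = 3e7, Ne = 1e6, f) {
  if (any(c(L, d, t_gen, Ne, f) <= 0)) {
    stop("all of L, d, t_gen, Ne, f must be positive")
  }
  if (f > 1) stop("f is a frequency and must be <= 1")
  2 * Ne * f * d * L / t_gen
}

# regional mutation rate per year under the same calibration
mu_region_per_year <- function(L, d, t_gen = 3e7, gens_per_year = 10) {
  d / (2 * t_gen) * L * gens_per_year
}

#' Rejection-ABC estimation of inversion parameters
#'
#' Models the inverted class as a population growing exponentially at a
#' constant rate since the inversion's formation.  Repeatedly draws theta ~
#' U(0, theta_prior_max) and alpha ~ U(0, alpha_prior_max), simulates a
#' coalescent sample of size `n`, and accepts the draw when the simulated
#' number of segregating sites and regional pi are both within `tolerance`
#' (relative) of the observed values; a zero-valued observation degenerates
#' the relative band to exact equality (the configuration seen when an
#' inversion carries no segregating sites at all).  Sampling stops at
#' `min_accept` acceptances.
#'
#' @param obs_s observed segregating-site count
#' @param obs_pi observed regional pairwise diversity (mismatch count scale)
#' @param n number of inverted haplotypes (>= 2)
#' @param theta_prior_max upper bound of the uniform theta prior
#'   (10 * [expected_theta()] in the standard configuration)
#' @param alpha_prior_max upper bound of the uniform growth-rate prior, in
#'   1/(4N0) units (default 100)
#' @param tolerance relative acceptance tolerance (default 0.05)
#' @param min_accept acceptances required (default 10000)
#' @param max_attempts simulation budget before giving up (default 2e7);
#'   exhausting it raises an error carrying the partial draws
#' @param batch_size simulations per vectorized batch
#' @param engine simulation engine, see [simulate_batch()]
#' @return object of class `abc_posterior`: list with `draws` (data.frame of
#'   accepted `alpha`, `theta`, `t_mrca`, `S`, `pi_region`),
#'   `acceptance_rate`, `attempts`, and the configuration
#' @export
abc_rejection <- function(obs_s, obs_pi, n, theta_prior_max,
                          alpha_prior_max = 100, tolerance = 0.05,
                          min_accept = 10000, max_attempts = 2e7,
                          batch_size = 50000, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n >= 2, obs_s >= 0, obs_pi >= 0, tolerance > 0, theta_prior_max > 0)
  draws <- list()
  accepted <- 0L
  attempts <- 0
  while (accepted < min_accept) {
    b <- as.integer(min(batch_size, max(1, max_attempts - attempts)))
    theta <- stats::runif(b, 0, theta_prior_max)
    alpha <- stats::runif(b, 0, alpha_prior_max)
    sim <- simulate_batch(n, theta, alpha, reps = b, engine = engine)
    attempts <- attempts + b
    ok_s <- if (obs_s > 0) abs(sim$S - obs_s) <= tolerance * obs_s else sim$S == 0L
    ok_pi <- if (obs_pi > 0) abs(sim$pi_region - obs_pi) <= tolerance * obs_pi else sim$pi_region == 0
    hit <- ok_s & ok_pi
    if (any(hit)) {
      draws[[length(draws) + 1L]] <- sim[hit, c("S", "pi_region", "t_mrca", "theta", "alpha")]
      accepted <- accepted + sum(hit)
    }
    if (attempts >= max_attempts && accepted < min_accept) {
      partial <- if (length(draws)) do.call(rbind, draws) else NULL
      cond <- simpleError(sprintf(
        "ABC budget exhausted: %d acceptances in %g attempts (rate %.3g)",
        accepted, attempts, accepted / attempts))
      cond$partial_draws <- partial
      stop(cond)
    }
  }
  draws <- do.call(rbind, draws)
  rownames(draws) <- NULL
  structure(list(
    draws = draws,
    acceptance_rate = accepted / attempts,
    attempts = attempts,
    config = list(obs_s = obs_s, obs_pi = obs_pi, n = n,
                  theta_prior_max = theta_prior_max,
                  alpha_prior_max = alpha_prior_max,
                  tolerance = tolerance, min_accept = min_accept)
  ), class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(
    "abc_posterior: %d accepted draws, acceptance rate %.3g (%g attempts)\n",
    nrow(x$draws), x$acceptance_rate, x$attempts))
  invisible(x)
}

#' Convert accepted ABC draws to ages in years
#'
#' Each accepted (theta, T_MRCA) pair implies an age: T_MRCA is in units of
#' 4N0 generations and theta = 4N0 mu_region, so T_MRCA * theta / mu_region
#' is the age in generations; dividing the per-generation regional mutation
#' rate calibration through by `gens_per_year` yields years.
#'
#' @param posterior an `abc_posterior`
#' @param L,d,t_gen as in [expected_theta()]
#' @param gens_per_year generations per year (default 10)
#' @return numeric vector of ages in years, one per accepted draw
#' @export
ages_from_posterior <- function(posterior, L, d, t_gen = 3e7, gens_per_year = 10) {
  if (!nrow(posterior$draws)) stop("posterior has no draws")
  mu_year <- mu_region_per_year(L, d, t_gen, gens_per_year)
  if (mu_year <= 0) stop("regional mutation rate must be positive")
  posterior$draws$t_mrca * posterior$draws$theta / mu_year
}

#' Median and 95% credible interval of a posterior sample
#'
#' Empirical quantiles with linear interpolation (R's default type-7
#' convention).
#'
#' @param values numeric vector (>= 1 value)
#' @return named numeric: `median`, `lower` (2.5th pct), `upper` (97.5th pct)
#' @export
posterior_summary <- function(values) {
  if (!length(values)) stop("empty posterior sample")
  q <- stats::quantile(values, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lower = q[2], upper = q[3])
}

#' Divergence-based inversion age
#'
#' Net divergence between arrangements — pi between inverted and standard
#' haplotypes minus pi among standard haplotypes — normalized by twice the
#' local per-site mutation rate per year (two lineages accumulate
#' substitutions).  Small or negative values are consistent with a very
#' recent origin and are returned as computed, with a flag.
#'
#' @param pi_between per-site pi between inverted and standard haplotypes
#' @param pi_std per-site pi among standard haplotypes
#' @param mu_site_per_year local per-site mutation rate per year (> 0)
#' @return list with `years` and logical `recent` (TRUE when years <= 0)
#' @export
divergence_age <- function(pi_between, pi_std, mu_site_per_year) {
  if (mu_site_per_year <= 0) stop("mutation rate must be positive")
  years <- (pi_between - pi_std) / (2 * mu_site_per_year)
  list(years = years, recent = years <= 0)
}
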