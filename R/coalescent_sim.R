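#' Sample a coalescent genealogy under exponential growth
#'
#' Single-population coalescent with exponential growth, in ms conventions:
#' time is measured in units of 4N0 generations, the backward population size
#' is N(t) = N0 exp(-alpha t), and with k active lineages the pairwise
#' coalescence rate at scaled time t is 2 exp(alpha t) per pair (k(k-1)
#' overall).  Waiting times are drawn by inverting the time change of the
#' cumulative hazard; for large alpha t the inversion is evaluated through
#' `log1p` so trees under strong growth do not overflow.
#'
#' @param n sample size (>= 2)
#' @param alpha exponential growth rate in units of 1/(4N0) generations
#'   (0 = constant size)
#' @return list with `t_mrca`, `t_total` (4N0 units), and `branches`: a list
#'   with `length` (numeric) and `leaves` (list of leaf index vectors below
#'   each branch)
#' @export
sample_genealogy <- function(n, alpha = 0) {
  stopifnot(n >= 2, alpha >= 0)
  active <- lapply(seq_len(n), identity)  # leaf sets
  birth <- numeric(n)
  t <- 0
  blen <- numeric(0)
  bleaves <- list()
  k <- n
  while (k > 1) {
    e <- stats::rexp(1)
    rate <- k * (k - 1)
    dt <- if (alpha == 0) e / rate else log1p(alpha * e * exp(-alpha * t) / rate) / alpha
    t <- t + dt
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    blen <- c(blen, t - birth[i], t - birth[j])
    bleaves <- c(bleaves, list(active[[i]], active[[j]]))
    active[[i]] <- c(active[[i]], active[[j]])
    birth[i] <- t
    active[[j]] <- NULL
    birth <- birth[-j]
    k <- k - 1L
  }
  list(t_mrca = t, t_total = sum(blen),
       branches = list(length = blen, leaves = bleaves))
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The mutation count is Poisson with mean theta times the total branch
#' length (both in 4N0 units); each mutation falls on a branch with
#' probability proportional to its length and is carried by every leaf below
#' it, so every column has between 1 and n-1 carriers.
#'
#' @param genealogy output of [sample_genealogy()]
#' @param theta population-scaled mutation rate per region (4N0 mu)
#' @return list with `haplotypes` (n x S 0/1 matrix, columns ordered by
#'   position) and `positions` (S values in (0,1))
#' @export
drop_mutations <- function(genealogy, theta) {
  stopifnot(theta >= 0)
  n <- max(unlist(genealogy$branches$leaves))
  m <- stats::rpois(1, theta * genealogy$t_total)
  if (m == 0) {
    return(list(haplotypes = matrix(0L, n, 0), positions = numeric(0)))
  }
  br <- sample.int(length(genealogy$branches$length), m, replace = TRUE,
                   prob = genealogy$branches$length)
  pos <- stats::runif(m)
  ord <- order(pos)
  hap <- matrix(0L, n, m)
  for (idx in seq_len(m)) {
    hap[genealogy$branches$leaves[[br[ord[idx]]]], idx] <- 1L
  }
  list(haplotypes = hap, positions = pos[ord])
}

#' Simulate batches of coalescent summary statistics
#'
#' Draws replicate genealogies and infinite-sites mutations, returning the
#' number of segregating sites, regional pairwise diversity, and tree times
#' per replicate.  `theta` and `alpha` may be scalars or vectors of length
#' `reps` (one parameter pair per replicate, as the ABC loop requires).  The
#' default engine is compiled; `engine = "r"` runs the reference
#' implementation ([sample_genealogy()] + [drop_mutations()]) and is used for
#' cross-checking.
#'
#' @param n sample size
#' @param theta,alpha scalar or length-`reps` parameter vectors
#' @param reps number of replicates
#' @param engine `"cpp"` or `"r"`
#' @return data.frame with columns `S`, `pi_region`, `t_mrca`, `t_total`,
#'   `theta`, `alpha`
#' @export
simulate_batch <- function(n, theta, alpha = 0, reps = 1L,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(reps >= 0)
  if (reps == 0) {
    return(data.frame(S = integer(), pi_region = numeric(), t_mrca = numeric(),
                      t_total = numeric(), theta = numeric(), alpha = numeric()))
  }
  theta <- rep_len(theta, reps)
  alpha <- rep_len(alpha, reps)
  if (engine == "cpp") {
    res <- coal_batch_cpp(as.integer(n), as.numeric(theta), as.numeric(alpha))
    res$theta <- theta
    res$alpha <- alpha
    return(res)
  }
  out <- vector("list", reps)
  denom <- n * (n - 1) / 2
  for (r in seq_len(reps)) {
    g <- sample_genealogy(n, alpha[r])
    mut <- drop_mutations(g, theta[r])
    cc <- colSums(mut$haplotypes)
    out[[r]] <- c(S = ncol(mut$haplotypes),
                  pi_region = sum(cc * (n - cc)) / denom,
                  t_mrca = g$t_mrca, t_total = g$t_total)
  }
  res <- as.data.frame(do.call(rbind, out))
  res$S <- as.integer(res$S)
  res$theta <- theta
  res$alpha <- alpha
  res
}
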