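# Neutrality statistics and their coalescent-simulation p-values.

# Standard constants for Tajima's D as functions of sample size.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Contrasts the mean pairwise difference estimator of theta with the
#' Watterson (segregating sites) estimator:
#' `D = (pi_hat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' sample-size constants. Negative values indicate an excess of rare
#' variants, as expected after population expansion.
#'
#' @inheritParams mean_pairwise_differences
#' @return Tajima's D.
#' @export
tajimas_d <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  n <- length(idx)
  if (n < 4) stop("Tajima's D needs n >= 4")
  S <- segregating_sites(aln, population)
  if (S < 1) stop("Tajima's D is undefined when no site is segregating")
  pihat <- mean_pairwise_differences(aln, population)
  k <- tajima_constants(n)
  (pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# log of unsigned Stirling numbers of the first kind, row n (k = 1..n),
# computed by the recurrence |s(n+1,k)| = |s(n,k-1)| + n*|s(n,k)| in log
# space. Cached per n.
.stirling_cache <- new.env(parent = emptyenv())
log_stirling_first <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  ls <- 0  # row 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in seq_len(n - 1)) {
      prev <- c(-Inf, ls)             # |s(m, k-1)| for k = 1..m+1
      scaled <- c(ls, -Inf) + log(m)  # m * |s(m, k)|
      ls <- pmax(prev, scaled) +
        log1p(exp(pmin(prev, scaled) - pmax(prev, scaled)))
      ls[is.nan(ls)] <- -Inf
    }
  }
  .stirling_cache[[key]] <- ls
  ls
}

# log P(K = k) for k = 1..n under the Ewens sampling distribution with
# parameter theta: P(K=k) = |s(n,k)| theta^k / theta^(n) (rising factorial).
ewens_log_pmf <- function(n, theta) {
  ls <- log_stirling_first(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  lp
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` where `S' = Pr(K >= K_obs | theta = pi_hat)`
#' under the Ewens sampling distribution, evaluated exactly through unsigned
#' Stirling numbers of the first kind in log space. Large negative values
#' indicate an excess of haplotypes relative to the pairwise-difference
#' estimate of theta, the classic signature of recent expansion.
#'
#' When `S'` reaches 0 or 1 (numerically, or because `K_obs = 1`), the
#' signed-infinity sentinel `+Inf` / `-Inf` is returned with a warning.
#'
#' @inheritParams mean_pairwise_differences
#' @return Fu's Fs.
#' @export
fus_fs <- function(aln, population = NULL) {
  idx <- aln_select(aln, population)
  n <- length(idx)
  if (n < 2) stop("Fu's Fs needs n >= 2")
  theta <- mean_pairwise_differences(aln, population)
  if (theta <= 0) stop("Fu's Fs is undefined when pi_hat = 0")
  k_obs <- haplotype_stats(aln, population)[["K"]]
  fs_from_theta(n, theta, k_obs)
}

# Core Fs computation from (n, theta, K_obs); shared with the simulation
# null so that observed and simulated values use identical code.
fs_from_theta <- function(n, theta, k_obs) {
  if (k_obs <= 1) return(-Inf)  # P(K >= 1) = 1: maximally negative direction
  lp <- ewens_log_pmf(n, theta)
  tail_lp <- lp[k_obs:n]
  mx <- max(tail_lp)
  log_sp <- mx + log(sum(exp(tail_lp - mx)))
  sp <- exp(log_sp)
  if (sp >= 1) {
    if (k_obs > 1) warning("Fu's Fs tail probability underflowed to 1")
    return(-Inf)
  }
  if (sp <= 0) {
    warning("Fu's Fs tail probability underflowed to 0")
    return(Inf)
  }
  log_sp - log1p(-sp)
}

#' Coalescent-simulation p-value for a neutrality statistic
#'
#' Simulates `n_sims` neutral constant-size coalescent datasets calibrated
#' to `theta_hat` (per-locus), computes the chosen statistic on each, and
#' returns the lower-tail fraction of simulated values `<= observed` — the
#' significance direction used when testing for population expansion.
#'
#' Replicates on which the statistic is undefined (no segregating site for
#' D, zero diversity for Fs) are redrawn, up to `10 * n_sims` attempts.
#'
#' @param stat_name `"D"` or `"Fs"`.
#' @param observed Observed statistic value.
#' @param n Sample size.
#' @param theta_hat Per-locus theta used to calibrate the null (typically
#'   the observed mean pairwise differences).
#' @param L Sequence length in bp.
#' @param n_sims Number of coalescent simulations (the conventional 1000 by
#'   default).
#' @param rng_seed Integer seed.
#' @return p-value in `[0, 1]`; the attribute `"n_redrawn"` counts redrawn
#'   replicates.
#' @export
neutrality_pvalue <- function(stat_name = c("D", "Fs"), observed, n,
                              theta_hat, L, n_sims = 1000, rng_seed = NULL) {
  stat_name <- match.arg(stat_name)
  if (n < 4) stop("simulation null needs n >= 4")
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (theta_hat <= 0) stop("theta_hat must be positive")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  vals <- numeric(n_sims)
  got <- 0L
  redrawn <- 0L
  max_tries <- 10L * n_sims
  tries <- 0L
  while (got < n_sims && tries < max_tries) {
    tries <- tries + 1L
    st <- sim_neutral_stat(stat_name, n, theta_hat, L)
    if (is.na(st)) {
      redrawn <- redrawn + 1L
      next
    }
    got <- got + 1L
    vals[got] <- st
  }
  if (got < n_sims) {
    stop("could not obtain ", n_sims, " defined replicates (", redrawn,
         " undefined draws)")
  }
  p <- mean(vals <= observed)
  attr(p, "n_redrawn") <- redrawn
  p
}

# One neutral constant-size replicate of D or Fs; NA when undefined.
# Uses the package coalescent engine with a single population whose size is
# chosen so that 2*NE*mu*L = theta_hat. Works on the integer tip states
# directly (no ambiguity codes in simulated data), via the same
# per-column-tally definitions as the alignment statistics.
sim_neutral_stat <- function(stat_name, n, theta_hat, L) {
  ne <- 1000
  mu <- theta_hat / (2 * ne * L)
  g <- sample_genealogy_single(n, ne, "pop")
  core <- sim_tip_states(g, mu, 1, rep(0.25, 4), L)
  if (is.null(core)) {
    return(NA_real_)  # S = 0: both statistics undefined
  }
  st <- core$states
  S <- 0L
  pair_diffs <- 0
  for (j in seq_len(ncol(st))) {
    cnt <- tabulate(st[, j], nbins = 4L)
    if (sum(cnt > 0) >= 2) S <- S + 1L
    pair_diffs <- pair_diffs + sum(cnt * (n - cnt)) / 2
  }
  pihat <- pair_diffs / (n * (n - 1) / 2)
  if (stat_name == "D") {
    if (S < 1) return(NA_real_)
    k <- tajima_constants(n)
    return((pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)))
  }
  if (pihat <= 0) return(NA_real_)
  k_obs <- length(unique(apply(st, 1, paste, collapse = ",")))
  fs_from_theta(n, pihat, k_obs)
}
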