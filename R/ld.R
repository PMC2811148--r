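#' Pairwise r-squared between two biallelic sites
#'
#' `r^2 = D^2 / (p(1-p) q(1-q))` with `D` the covariance of the allelic
#' indicators across haplotypes.
#'
#' @param a,b Binary (0/1) haplotype vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
#' @examples
#' pairwise_r2(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1
#' pairwise_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
pairwise_r2 <- function(a, b) {
  stopifnot(length(a) == length(b), all(a %in% 0:1), all(b %in% 0:1))
  pa <- mean(a); pb <- mean(b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    abort_classed("synthassoc_monomorphic",
                  "r-squared undefined for a monomorphic column")
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# all rare x common r^2 values between two column sets of one panel matrix
cross_r2 <- function(a, b) {
  n <- nrow(a)
  pa <- colMeans(a); pb <- colMeans(b)
  d <- crossprod(a, b) / n - outer(pa, pb)
  d^2 / outer(pa * (1 - pa), pb * (1 - pb))
}

#' Mean and variance of r-squared between rare and common sites
#'
#' The simplified two-locus experiment: for each recombination rate,
#' simulate `n_sims` independent pairs of loci separated by that rate, take
#' every cross-locus pair of a rare site (derived frequency in
#' `rare_window`, locus 0) and a common site (minor allele frequency at
#' least `common_min`, locus 1), and pool the r-squared values. Simulations
#' with no eligible pair contribute nothing but are counted.
#'
#' @param rates Ascending vector of per-meiosis recombination probabilities.
#' @param n_sims Simulations per rate.
#' @param params A [sim_params()] supplying the sample size, Ne, mutation
#'   rate and per-locus length (`fragment_length`).
#' @param rare_window Derived-frequency window defining "rare".
#' @param common_min Minimum minor-allele frequency defining "common".
#' @param seed Optional integer seed.
#' @return Data frame of class `ld_moments`: `rate`, `mean_r2`, `var_r2`,
#'   `se_mean` (standard error of `mean_r2` treating simulations as
#'   independent units), `n_pairs`, `n_used` (simulations contributing at
#'   least one pair) and `n_sims`.
#' @export
ld_moment_curve <- function(rates, n_sims, params = sim_params(),
                            rare_window = c(0.005, 0.02), common_min = 0.05,
                            seed = NULL) {
  stopifnot(!is.unsorted(rates), n_sims >= 1)
  seeds <- derive_seeds(seed, length(rates) * n_sims)
  out <- data.frame(rate = rates, mean_r2 = NA_real_, var_r2 = NA_real_,
                    se_mean = NA_real_, n_pairs = 0L, n_used = 0L,
                    n_sims = as.integer(n_sims))
  for (i in seq_along(rates)) {
    s1 <- 0; s2 <- 0; np <- 0L
    sim_mean <- numeric(0); sim_w <- numeric(0)
    for (r in seq_len(n_sims)) {
      pan <- simulate_linked_pair(params$n_haplotypes, rates[i], params,
                                  seed = seeds[[(i - 1L) * n_sims + r]])
      if (n_sites(pan) == 0L) next
      maf <- pmin(pan$freq, 1 - pan$freq)
      rare <- which(pan$fragment == 0L & pan$freq >= rare_window[1] &
                    pan$freq <= rare_window[2])
      comm <- which(pan$fragment == 1L & maf >= common_min)
      if (!length(rare) || !length(comm)) next
      m <- as.matrix(pan)
      r2 <- cross_r2(m[, rare, drop = FALSE], m[, comm, drop = FALSE])
      s1 <- s1 + sum(r2); s2 <- s2 + sum(r2^2); np <- np + length(r2)
      sim_mean <- c(sim_mean, mean(r2)); sim_w <- c(sim_w, length(r2))
    }
    if (np > 0L) {
      mu <- s1 / np
      out$mean_r2[i] <- mu
      out$var_r2[i] <- if (np > 1L) (s2 - np * mu^2) / (np - 1L) else NA_real_
      out$n_pairs[i] <- np
      out$n_used[i] <- length(sim_mean)
      if (length(sim_mean) > 1L) {
        # weighted between-simulation spread of the pooled mean
        wm <- sum(sim_w * sim_mean) / sum(sim_w)
        out$se_mean[i] <- sqrt(sum(sim_w^2 * (sim_mean - wm)^2)) / sum(sim_w)
      }
    }
  }
  class(out) <- c("ld_moments", "data.frame")
  out
}
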