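#' Coalescent simulation parameters
#'
#' Parameter set for the neutral coalescent haplotype simulator. The region
#' is divided into `n_fragments` fragments of `fragment_length` bp; mutation
#' follows the infinite-sites model within fragments and crossover occurs
#' only at fragment boundaries, with per-meiosis probability
#' `recomb_between_fragments` between each pair of adjacent fragments.
#'
#' @param n_haplotypes Number of sampled haplotypes (even, at least 4).
#'   Default 10,000.
#' @param effective_pop_size Effective population size Ne (constant).
#'   Default 10,000.
#' @param mutation_rate Mutation rate per bp per generation. Default 1e-8.
#' @param region_length Region length in bp. Default 100,000.
#' @param fragment_length Fragment length in bp. Default 500.
#' @param n_fragments Number of fragments; must satisfy
#'   `n_fragments * fragment_length == region_length`.
#' @param recomb_between_fragments Per-meiosis crossover probability between
#'   adjacent fragments. 0 means a single genealogical tree for the whole
#'   region.
#' @param seed Optional integer seed stored with the parameters and used by
#'   [simulate_panel()] when no explicit seed is given.
#'
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_haplotypes = 100, region_length = 10000, n_fragments = 20)
#' panel <- simulate_panel(p, seed = 1)
sim_params <- function(n_haplotypes = 10000,
                       effective_pop_size = 10000,
                       mutation_rate = 1e-8,
                       region_length = 100000,
                       fragment_length = 500,
                       n_fragments = round(region_length / fragment_length),
                       recomb_between_fragments = 0,
                       seed = NULL) {
  stopifnot(n_haplotypes >= 4, n_haplotypes %% 2 == 0,
            effective_pop_size > 0,
            mutation_rate >= 0, region_length > 0,
            fragment_length > 0, n_fragments >= 1,
            recomb_between_fragments >= 0)
  if (abs(n_fragments * fragment_length - region_length) > 1e-6)
    stop("n_fragments * fragment_length must equal region_length")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 effective_pop_size = effective_pop_size,
                 mutation_rate = mutation_rate,
                 region_length = region_length,
                 fragment_length = fragment_length,
                 n_fragments = as.integer(n_fragments),
                 recomb_between_fragments = recomb_between_fragments,
                 seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Coalescent simulation parameters\n")
  cat(sprintf("  haplotypes: %d   Ne: %g   mu: %g /bp/gen\n",
              x$n_haplotypes, x$effective_pop_size, x$mutation_rate))
  cat(sprintf("  region: %g bp in %d fragments of %g bp\n",
              x$region_length, x$n_fragments, x$fragment_length))
  cat(sprintf("  recombination between fragments: %g per meiosis\n",
              x$recomb_between_fragments))
  invisible(x)
}

#' Simulate a haplotype panel under the coalescent
#'
#' Draws one gene genealogy (an ancestral recombination graph when
#' `recomb_between_fragments > 0`) for `n_haplotypes` samples and drops
#' infinite-sites mutations on it, returning the segregating sites. Scaled
#' rates are `theta = 4 * Ne * mu * L` for mutation and `rho = 4 * Ne * c`
#' per fragment boundary for recombination.
#'
#' Only segregating sites are returned: the derived-allele count is strictly
#' between 0 and `n_haplotypes` at every site. When no site segregates
#' (e.g. `mutation_rate = 0`) the panel is returned empty and a warning of
#' class `synthassoc_degenerate_panel` is signalled so the caller can decide
#' to redraw.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (defaults to `params$seed`). The same seed
#'   reproduces the panel bit for bit.
#' @return An object of class `hap_panel` with elements `n_hap`,
#'   `positions` (bp offsets from the region start, 0-based, strictly
#'   increasing), `fragment` (0-based fragment index per site),
#'   `carriers` (list of 1-based haplotype indices carrying the derived
#'   allele at each site), `freq` (derived-allele frequency per site) and
#'   the event counts of the underlying graph. Use [as.matrix()] for the
#'   dense 0/1 haplotype-by-site matrix.
#' @export
simulate_panel <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  theta_frag <- 4 * params$effective_pop_size * params$mutation_rate *
    params$fragment_length
  rho_b <- 4 * params$effective_pop_size * params$recomb_between_fragments
  raw <- with_seed(seed, .sim_fragment_panel(params$n_haplotypes,
                                             params$n_fragments,
                                             params$fragment_length,
                                             theta_frag, rho_b))
  carriers <- lapply(raw$carriers, function(v) v + 1L)
  panel <- structure(list(n_hap = params$n_haplotypes,
                          positions = raw$positions,
                          fragment = raw$fragment,
                          carriers = carriers,
                          freq = raw$count / params$n_haplotypes,
                          n_rec_events = raw$n_rec_events,
                          n_coal_events = raw$n_coal_events,
                          params = params,
                          seed = seed),
                     class = "hap_panel")
  if (n_sites(panel) == 0L)
    signal_degenerate_panel("panel has zero segregating sites")
  panel
}

#' Simulate a linked pair of loci
#'
#' Convenience wrapper for the two-locus design: two fragments with
#' recombination only between them. Used by [ld_moment_curve()].
#'
#' @param n_haplotypes Sample size.
#' @param recomb_rate Per-meiosis recombination probability between the two
#'   loci.
#' @param params A [sim_params()] object supplying Ne, the mutation rate and
#'   the per-locus length (`fragment_length`); its region/fragment layout is
#'   overridden.
#' @param seed Integer seed.
#' @return A `hap_panel` whose `fragment` field is 0 for the first locus and
#'   1 for the second.
#' @export
simulate_linked_pair <- function(n_haplotypes, recomb_rate,
                                 params = sim_params(), seed = NULL) {
  p2 <- sim_params(n_haplotypes = n_haplotypes,
                   effective_pop_size = params$effective_pop_size,
                   mutation_rate = params$mutation_rate,
                   region_length = 2 * params$fragment_length,
                   fragment_length = params$fragment_length,
                   n_fragments = 2L,
                   recomb_between_fragments = recomb_rate)
  suppressWarnings(simulate_panel(p2, seed = seed))
}

#' Number of segregating sites in a panel
#' @param panel A `hap_panel`.
#' @return Integer site count.
#' @export
n_sites <- function(panel) length(panel$positions)

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes, %d segregating sites, %g bp\n",
              x$n_hap, n_sites(x), x$params$region_length))
  cat(sprintf("  recombination events: %g, coalescences: %g\n",
              x$n_rec_events, x$n_coal_events))
  invisible(x)
}

#' Dense allele matrix of a panel
#'
#' @param x A `hap_panel`.
#' @param ... Unused.
#' @return Integer matrix (haplotype x site) of 0 = ancestral / 1 = derived.
#' @export
as.matrix.hap_panel <- function(x, ...) {
  m <- matrix(0L, nrow = x$n_hap, ncol = n_sites(x))
  for (j in seq_len(n_sites(x))) m[x$carriers[[j]], j] <- 1L
  m
}

#' Diploid genotypes for chosen haplotype pairs
#'
#' Additive genotype codes (0/1/2 copies of the derived allele) for
#' individuals formed by pairing panel haplotypes, without materialising the
#' full panel matrix.
#'
#' @param panel A `hap_panel`.
#' @param h1,h2 Integer vectors of haplotype indices (1-based), one pair per
#'   individual.
#' @param sites Panel site indices to include (default all).
#' @return Integer matrix, individuals x sites.
#' @export
cohort_genotypes <- function(panel, h1, h2, sites = seq_len(n_sites(panel))) {
  stopifnot(length(h1) == length(h2))
  g <- matrix(0L, nrow = length(h1), ncol = length(sites))
  memb <- logical(panel$n_hap)
  for (j in seq_along(sites)) {
    carr <- panel$carriers[[sites[j]]]
    memb[carr] <- TRUE
    g[, j] <- memb[h1] + memb[h2]
    memb[carr] <- FALSE
  }
  g
}

#' Count four-gamete violations in a panel
#'
#' Two biallelic sites violate the four-gamete test when all four haplotypes
#' (00, 01, 10, 11) are observed, which under infinite sites implies
#' recombination between them. With `recomb_between_fragments = 0` the whole
#' region shares one tree, so the count must be exactly zero.
#'
#' @param panel A `hap_panel`.
#' @param sites Optional site subset (indices).
#' @return Number of site pairs exhibiting all four gametes.
#' @export
four_gamete_violations <- function(panel, sites = seq_len(n_sites(panel))) {
  if (length(sites) < 2) return(0L)
  a <- as.matrix(panel)[, sites, drop = FALSE]
  n <- nrow(a)
  c1 <- colSums(a)
  n11 <- crossprod(a)
  n10 <- outer(c1, rep(1, length(c1))) - n11
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  viol <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  sum(viol[upper.tri(viol)])
}
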