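#' Disease model specification
#'
#' Dominant penetrance model at the locus level: an individual carrying at
#' least one derived allele at any causal site is affected with probability
#' `gamma`, all other individuals with the baseline probability `phi`. The
#' genotypic relative risk is `grr = gamma / phi`. Causal sites are rare by
#' construction: their panel derived-allele frequency must fall inside
#' `freq_window`.
#'
#' @param phi Baseline disease probability for non-carriers.
#' @param grr Genotypic relative risk `gamma / phi` (give either `grr` or
#'   `gamma`).
#' @param gamma Carrier disease probability; defaults to `phi * grr`.
#' @param n_causal Number of rare causal sites k.
#' @param freq_window Closed interval of admissible derived-allele
#'   frequencies for causal sites. Default `c(0.005, 0.02)`.
#' @return An object of class `disease_spec`.
#' @export
#' @examples
#' disease_spec(phi = 0.01, grr = 4, n_causal = 9)
disease_spec <- function(phi = 0.01, grr = NULL, gamma = NULL,
                         n_causal = 1, freq_window = c(0.005, 0.02)) {
  if (is.null(gamma)) {
    if (is.null(grr)) stop("give either grr or gamma")
    gamma <- phi * grr
  }
  if (is.null(grr)) grr <- gamma / phi  # Inf when phi = 0 (deterministic limit)
  stopifnot(phi >= 0, gamma >= phi, gamma <= 1,
            n_causal >= 0, length(freq_window) == 2,
            freq_window[1] <= freq_window[2])
  if (phi > 0) stopifnot(abs(grr - gamma / phi) < 1e-12)
  structure(list(phi = phi, gamma = gamma, grr = grr,
                 n_causal = as.integer(n_causal),
                 freq_window = freq_window),
            class = "disease_spec")
}

#' @export
print.disease_spec <- function(x, ...) {
  cat(sprintf(
    "Disease model: phi = %g, gamma = %g (GRR = %g), %d causal site(s) in [%g, %g]\n",
    x$phi, x$gamma, x$grr, x$n_causal, x$freq_window[1], x$freq_window[2]))
  invisible(x)
}

#' Assign rare causal sites on a panel
#'
#' Draws `spec$n_causal` distinct sites uniformly without replacement from
#' the panel sites whose derived-allele frequency lies in
#' `spec$freq_window`. Frequencies are measured on the full panel, before
#' any cohort is ascertained.
#'
#' @param panel A `hap_panel`.
#' @param spec A [disease_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `causal_set` with `sites` (panel indices) and
#'   `freq`. When fewer eligible sites exist than requested, an error of
#'   class `synthassoc_redraw` is raised, signalling that the genealogy
#'   should be redrawn.
#' @export
select_causal_sites <- function(panel, spec, seed = NULL) {
  eligible <- which(panel$freq >= spec$freq_window[1] &
                    panel$freq <= spec$freq_window[2])
  if (length(eligible) < spec$n_causal)
    abort_classed("synthassoc_redraw",
                  sprintf("only %d eligible causal site(s), need %d",
                          length(eligible), spec$n_causal))
  idx <- if (spec$n_causal == 0L) integer(0)
         else sort(with_seed(seed, resample(eligible, spec$n_causal)))
  structure(list(sites = idx, freq = panel$freq[idx]), class = "causal_set")
}

#' Haplotype-level carrier indicator
#' @param panel A `hap_panel`.
#' @param causal A `causal_set`.
#' @return Logical vector: does each haplotype carry a derived allele at any
#'   causal site?
#' @export
carrier_haplotypes <- function(panel, causal) {
  carrier <- logical(panel$n_hap)
  for (s in causal$sites) carrier[panel$carriers[[s]]] <- TRUE
  carrier
}

#' Disease class size
#'
#' The disease class is the proportion of panel haplotypes carrying one or
#' more causal (derived) alleles.
#'
#' @inheritParams carrier_haplotypes
#' @return Fraction in `[0, 1]`.
#' @export
disease_class_size <- function(panel, causal) {
  mean(carrier_haplotypes(panel, causal))
}

#' Ascertain a case/control cohort from a panel
#'
#' Individuals are formed by drawing two haplotypes with replacement from
#' the panel. A carrier (>= 1 causal derived allele on either haplotype) is
#' affected with probability `gamma`, a non-carrier with probability `phi`.
#' Sampling continues until `n_per_arm` cases and `n_per_arm` controls are
#' collected; surplus individuals are discarded.
#'
#' @param panel A `hap_panel`.
#' @param causal A `causal_set` on that panel.
#' @param spec A [disease_spec()].
#' @param n_per_arm Cases and controls per arm.
#' @param seed Optional integer seed.
#' @param sites Panel site indices for which genotypes are materialised
#'   (default all sites).
#' @param max_draw Attempt cap on total individuals generated; exceeding it
#'   raises an error of class `synthassoc_infeasible` rather than silently
#'   truncating. Default 1e7.
#' @return An object of class `cohort`: haplotype pair indices `h1`/`h2`,
#'   logical `status` (TRUE = case), the additive genotype matrix
#'   (individuals x `sites`), `site_index`, `positions`, `fragment`, and
#'   arm counts.
#' @export
sample_cohort <- function(panel, causal, spec, n_per_arm, seed = NULL,
                          sites = seq_len(n_sites(panel)), max_draw = 1e7) {
  stopifnot(n_per_arm >= 1)
  carrier_h <- carrier_haplotypes(panel, causal)
  with_seed(seed, {
    q <- 1 - (1 - mean(carrier_h))^2         # diploid carrier probability
    p_case <- q * spec$gamma + (1 - q) * spec$phi
    batch <- min(max(20000, ceiling(1.5 * n_per_arm / max(p_case, 1e-4))), 2e6)
    need_case <- n_per_arm; need_ctrl <- n_per_arm
    acc_h1 <- integer(0); acc_h2 <- integer(0); acc_st <- logical(0)
    total <- 0
    while (need_case > 0 || need_ctrl > 0) {
      if (total >= max_draw)
        abort_classed("synthassoc_infeasible",
                      sprintf("case/control quota not reached after %g individuals",
                              total))
      m <- as.integer(min(batch, max_draw - total)); total <- total + m
      h1 <- sample.int(panel$n_hap, m, replace = TRUE)
      h2 <- sample.int(panel$n_hap, m, replace = TRUE)
      carrier <- carrier_h[h1] | carrier_h[h2]
      is_case <- runif(m) < ifelse(carrier, spec$gamma, spec$phi)
      take_case <- which(is_case)
      if (length(take_case) > need_case) take_case <- take_case[seq_len(need_case)]
      take_ctrl <- which(!is_case)
      if (length(take_ctrl) > need_ctrl) take_ctrl <- take_ctrl[seq_len(need_ctrl)]
      keep <- c(take_case, take_ctrl)
      acc_h1 <- c(acc_h1, h1[keep]); acc_h2 <- c(acc_h2, h2[keep])
      acc_st <- c(acc_st, is_case[keep])
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
    g <- cohort_genotypes(panel, acc_h1, acc_h2, sites)
    structure(list(h1 = acc_h1, h2 = acc_h2, status = acc_st,
                   genotypes = g,
                   site_index = as.integer(sites),
                   positions = panel$positions[sites],
                   fragment = panel$fragment[sites],
                   n_cases = sum(acc_st), n_controls = sum(!acc_st),
                   n_drawn = total),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d controls (%g individuals drawn), %d site(s)\n",
              x$n_cases, x$n_controls, x$n_drawn, ncol(x$genotypes)))
  invisible(x)
}
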