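#' Parameter grid specification
#'
#' Enumerates the cells of the power-simulation grid: every combination of
#' genotypic relative risk, number of causal sites, per-arm sample size,
#' baseline risk and recombination rate, with a fixed number of replicate
#' simulations per cell. Replicate seeds are derived deterministically from
#' the master seed.
#'
#' @param grr_values Genotypic relative risks. Default `c(2, 3, 4, 5, 6)`.
#' @param n_causal_values Numbers of rare causal sites. Default
#'   `c(1, 3, 5, 7, 9)`.
#' @param n_per_arm_values Cases (= controls) per cohort. Default
#'   `c(1000, 2000, 3000)`.
#' @param phi_values Baseline disease probabilities. Default
#'   `c(0.01, 0.1)`.
#' @param recomb_values Between-fragment recombination probabilities.
#'   Default `0` (single tree per region).
#' @param replicates Replicates per cell.
#' @param seed Master seed.
#' @param params Coalescent parameters shared by all cells (the
#'   recombination entry is overridden per cell).
#' @return An object of class `grid_spec` with a `cells` data frame.
#' @export
grid_spec <- function(grr_values = c(2, 3, 4, 5, 6),
                      n_causal_values = c(1, 3, 5, 7, 9),
                      n_per_arm_values = c(1000, 2000, 3000),
                      phi_values = c(0.01, 0.1),
                      recomb_values = 0,
                      replicates = 20,
                      seed = NULL,
                      params = sim_params()) {
  cells <- expand.grid(grr = grr_values, n_causal = n_causal_values,
                       n_per_arm = n_per_arm_values, phi = phi_values,
                       recomb = recomb_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells$cell <- seq_len(nrow(cells))
  structure(list(cells = cells, replicates = as.integer(replicates),
                 seed = seed, params = params),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Simulation grid: %d cells x %d replicates\n",
              nrow(x$cells), x$replicates))
  invisible(x)
}

#' Run one complete simulation replicate
#'
#' One "simulation" in the sense of the study design: draw a gene
#' genealogy, assign rare causal sites (redrawing the genealogy when too
#' few sites fall in the causal frequency window), ascertain a cohort,
#' scan the common variants, and — if a genome-wide significant common hit
#' exists — run the conditional scan with the top hit as covariate. Causal
#' sites are additionally tested individually so the strongest causal and
#' strongest common associations can be compared.
#'
#' @param params A [sim_params()]; its `recomb_between_fragments` decides
#'   whether same-fragment masking applies.
#' @param dspec A [disease_spec()].
#' @param n_per_arm Cases (= controls) in the cohort.
#' @param seed Integer seed for the replicate.
#' @param gw_threshold Genome-wide significance threshold (strict `<`).
#'   Default 1e-8.
#' @param max_redraws Genealogy redraw cap when the causal window is empty.
#' @param conditional Run the conditional scan for significant replicates.
#' @param site_prefilter_maf For very large panels, materialise cohort
#'   genotypes only for causal sites and sites with panel MAF at least this
#'   value (`NULL` = keep all sites).
#' @param test Association test passed to [logistic_scan()].
#' @param keep_objects Attach the simulated `panel`, `causal` set and
#'   `cohort` to the result as attributes (used by downstream analyses
#'   that need more than the summary record).
#' @return One-row data frame (a replicate record) with the cell
#'   parameters, disease-class size, minimum common and causal p-values,
#'   top-hit summary (position, beta, risk allele and its frequency in the
#'   pooled cohort and in controls), significance flags, conditional-scan
#'   outcome and bookkeeping counters.
#' @export
run_replicate <- function(params, dspec, n_per_arm, seed = NULL,
                          gw_threshold = 1e-8, max_redraws = 50L,
                          conditional = TRUE, site_prefilter_maf = NULL,
                          test = "wald", keep_objects = FALSE) {
  seeds <- derive_seeds(seed, max_redraws + 3L)
  redraws <- 0L
  panel <- NULL; causal <- NULL
  for (attempt in seq_len(max_redraws)) {
    cand <- suppressWarnings(simulate_panel(params, seed = seeds[[attempt]]))
    causal <- tryCatch(select_causal_sites(cand, dspec,
                                           seed = seeds[[max_redraws + 1L]]),
                       synthassoc_redraw = function(e) NULL)
    if (!is.null(causal)) { panel <- cand; break }
    redraws <- redraws + 1L
  }
  if (is.null(panel))
    abort_classed("synthassoc_redraw",
                  sprintf("no genealogy with %d eligible causal sites in %d draws",
                          dspec$n_causal, max_redraws))

  keep_sites <- if (is.null(site_prefilter_maf)) seq_len(n_sites(panel))
  else sort(union(causal$sites,
                  which(pmin(panel$freq, 1 - panel$freq) >= site_prefilter_maf)))
  cohort <- sample_cohort(panel, causal, dspec, n_per_arm,
                          seed = seeds[[max_redraws + 2L]], sites = keep_sites)

  fragment_exclusion <- params$recomb_between_fragments > 0
  common <- eligible_common_sites(panel, causal, cohort,
                                  fragment_exclusion = fragment_exclusion)
  tab <- logistic_scan(cohort, common, test = test,
                       masked = attr(common, "masked"))
  hit <- top_hit(tab)
  gw <- !is.null(hit) && hit$p < gw_threshold

  causal_tab <- logistic_scan(cohort, causal$sites, test = test)
  min_causal_p <- if (any(is.finite(causal_tab$p))) min(causal_tab$p, na.rm = TRUE)
                  else NA_real_

  cond_min_p <- NA_real_
  if (gw && conditional && nrow(tab) > 1L) {
    ctab <- conditional_scan(cohort, common, hit$site, test = test)
    chit <- top_hit(ctab)
    if (!is.null(chit)) cond_min_p <- chit$p
  }

  raf <- raf_ctrl <- NA_real_
  risk_allele <- NA_character_
  if (!is.null(hit)) {
    col <- match(hit$site, cohort$site_index)
    fbar <- mean(cohort$genotypes[, col]) / 2
    fbar_ctrl <- mean(cohort$genotypes[!cohort$status, col]) / 2
    risk_allele <- hit$risk_allele
    raf <- if (identical(risk_allele, "derived")) fbar else 1 - fbar
    raf_ctrl <- if (identical(risk_allele, "derived")) fbar_ctrl else 1 - fbar_ctrl
  }

  out <- data.frame(grr = dspec$grr, phi = dspec$phi, n_causal = dspec$n_causal,
             n_per_arm = n_per_arm,
             recomb = params$recomb_between_fragments,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             n_redraws = redraws,
             n_sites = n_sites(panel),
             n_common_tested = nrow(tab),
             n_masked = nrow(attr(tab, "masked")),
             n_flagged = sum(tab$fit_status != "ok"),
             disease_class = disease_class_size(panel, causal),
             min_common_p = if (is.null(hit)) NA_real_ else hit$p,
             top_site = if (is.null(hit)) NA_integer_ else hit$site,
             top_pos = if (is.null(hit)) NA_real_ else hit$pos,
             top_beta = if (is.null(hit)) NA_real_ else hit$beta,
             top_maf = if (is.null(hit)) NA_real_ else hit$maf,
             risk_allele = risk_allele,
             raf = raf, raf_controls = raf_ctrl,
             gw_significant = gw,
             min_causal_p = min_causal_p,
             causal_stronger = if (is.na(min_causal_p) || is.null(hit)) NA
                               else min_causal_p < hit$p,
             cond_min_p = cond_min_p,
             cond_gw = if (gw) isTRUE(cond_min_p < gw_threshold) else NA,
             cond_none_05 = if (gw) isTRUE(is.na(cond_min_p) || cond_min_p > 0.05)
                            else NA,
             stringsAsFactors = FALSE)
  if (keep_objects) {
    attr(out, "panel") <- panel
    attr(out, "causal") <- causal
    attr(out, "cohort") <- cohort
  }
  out
}

#' Run the full simulation grid
#'
#' Executes [run_replicate()] for every cell of a [grid_spec()] and
#' aggregates per-cell and pooled summaries.
#'
#' @param grid A [grid_spec()].
#' @param verbose Print a line per cell.
#' @param ... Passed on to [run_replicate()].
#' @return A `grid_result` list: `replicates` (all replicate records),
#'   `cells` (per-cell proportions with binomial standard errors) and
#'   `pooled` (overall proportions).
#' @export
run_grid <- function(grid, verbose = FALSE, ...) {
  cells <- grid$cells
  reps <- grid$replicates
  seeds <- derive_seeds(grid$seed, nrow(cells) * reps)
  out <- vector("list", nrow(cells) * reps)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    params <- grid$params
    params$recomb_between_fragments <- cell$recomb
    dspec <- disease_spec(phi = cell$phi, grr = cell$grr,
                          n_causal = cell$n_causal)
    for (r in seq_len(reps)) {
      k <- (ci - 1L) * reps + r
      rec <- run_replicate(params, dspec, cell$n_per_arm,
                           seed = seeds[[k]], ...)
      rec$cell <- cell$cell
      out[[k]] <- rec
    }
    if (verbose)
      message(sprintf("cell %d/%d (GRR=%g k=%d n=%d phi=%g rec=%g) done",
                      ci, nrow(cells), cell$grr, cell$n_causal,
                      cell$n_per_arm, cell$phi, cell$recomb))
  }
  replicates <- do.call(rbind, out)
  structure(list(replicates = replicates,
                 cells = summarize_cells(replicates),
                 pooled = summarize_pooled(replicates),
                 grid = grid),
            class = "grid_result")
}

summarize_cells <- function(replicates) {
  sp <- split(replicates, replicates$cell)
  rows <- lapply(sp, function(d) {
    n <- nrow(d)
    p_common <- mean(d$gw_significant)
    p_causal <- mean(d$min_causal_p < 1e-8, na.rm = TRUE)
    data.frame(cell = d$cell[1], grr = d$grr[1], n_causal = d$n_causal[1],
               n_per_arm = d$n_per_arm[1], phi = d$phi[1], recomb = d$recomb[1],
               n = n,
               prop_gw_common = p_common,
               se_gw_common = binom_se(p_common, n),
               prop_gw_causal = p_causal,
               prop_causal_stronger = mean(d$causal_stronger, na.rm = TRUE),
               mean_disease_class = mean(d$disease_class))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell), ]
}

summarize_pooled <- function(replicates) {
  n <- nrow(replicates)
  p_common <- mean(replicates$gw_significant)
  cs <- replicates$causal_stronger
  ok <- !is.na(cs)
  # strict: min causal p < min common p, per replicate.
  # synth: the causal variant is only "beaten" when the winning common
  # variant is itself a genome-wide significant (synthetic) association.
  synth <- !(replicates$gw_significant[ok] & !cs[ok])
  list(n_replicates = n,
       prop_gw_common = p_common,
       se_gw_common = binom_se(p_common, n),
       prop_gw_causal = mean(replicates$min_causal_p < 1e-8, na.rm = TRUE),
       prop_causal_stronger = mean(cs[ok]),
       se_causal_stronger = binom_se(mean(cs[ok]), sum(ok)),
       prop_causal_stronger_synth = mean(synth),
       se_causal_stronger_synth = binom_se(mean(synth), sum(ok)))
}

#' @export
print.grid_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("Grid result: %d replicates over %d cells\n",
              p$n_replicates, nrow(x$cells)))
  cat(sprintf("  GW-significant common variant: %.1f%% (SE %.1f%%)\n",
              100 * p$prop_gw_common, 100 * p$se_gw_common))
  cat(sprintf("  causal stronger than common:  %.1f%%\n",
              100 * p$prop_causal_stronger))
  invisible(x)
}

#' Null-control experiment
#'
#' Tests the common variants of one genealogy against phenotypes generated
#' by an independent genealogy with the same parameter settings. The two
#' are unlinked by construction, so any association is spurious; the scan
#' p-values should be uniform and none should reach genome-wide
#' significance at realistic test counts.
#'
#' @param params A [sim_params()].
#' @param dspec A [disease_spec()] used for the phenotype-generating
#'   genealogy.
#' @param n_per_arm Cases (= controls).
#' @param replicates Number of independent replicate pairs.
#' @param seed Master seed.
#' @param gw_threshold Genome-wide threshold. Default 1e-8.
#' @return List: `n_gw_hits` (tests below the threshold, pooled),
#'   `p_values` (all scan p-values pooled), `n_tests`, and the per-replicate
#'   record data frame.
#' @export
null_control <- function(params, dspec, n_per_arm, replicates, seed = NULL,
                         gw_threshold = 1e-8) {
  seeds <- derive_seeds(seed, 4L * replicates)
  pvals <- vector("list", replicates)
  recs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    s <- seeds[(4L * (r - 1L) + 1L):(4L * r)]
    # phenotype-generating genealogy B (redraw until causal sites exist)
    status <- NULL
    for (attempt in 1:50) {
      panel_b <- suppressWarnings(simulate_panel(params, seed = s[[1]]))
      causal_b <- tryCatch(select_causal_sites(panel_b, dspec, seed = s[[2]]),
                           synthassoc_redraw = function(e) NULL)
      if (!is.null(causal_b)) {
        status <- sample_cohort(panel_b, causal_b, dspec, n_per_arm,
                                seed = s[[3]], sites = causal_b$sites)$status
        break
      }
      s[[1]] <- s[[1]] + 1L
    }
    if (is.null(status)) next
    # genotype-providing genealogy A, individuals drawn independently
    panel_a <- suppressWarnings(simulate_panel(params, seed = s[[4]]))
    if (n_sites(panel_a) == 0L) next
    n_ind <- length(status)
    geno <- with_seed(s[[4]] + 1L, {
      h1 <- sample.int(panel_a$n_hap, n_ind, replace = TRUE)
      h2 <- sample.int(panel_a$n_hap, n_ind, replace = TRUE)
      list(h1 = h1, h2 = h2, g = cohort_genotypes(panel_a, h1, h2))
    })
    cohort <- structure(list(h1 = geno$h1, h2 = geno$h2, status = status,
                             genotypes = geno$g,
                             site_index = seq_len(n_sites(panel_a)),
                             positions = panel_a$positions,
                             fragment = panel_a$fragment,
                             n_cases = sum(status), n_controls = sum(!status),
                             n_drawn = n_ind),
                        class = "cohort")
    empty_causal <- structure(list(sites = integer(0), freq = numeric(0)),
                              class = "causal_set")
    common <- eligible_common_sites(panel_a, empty_causal, cohort)
    tab <- logistic_scan(cohort, common, masked = attr(common, "masked"))
    pvals[[r]] <- tab$p[is.finite(tab$p)]
    recs[[r]] <- data.frame(replicate = r, n_tests = sum(is.finite(tab$p)),
                            min_p = suppressWarnings(min(tab$p, na.rm = TRUE)),
                            n_gw = sum(tab$p < gw_threshold, na.rm = TRUE))
  }
  p <- unlist(pvals)
  list(n_gw_hits = sum(p < gw_threshold),
       p_values = p,
       n_tests = length(p),
       replicates = do.call(rbind, recs))
}

#' Secondary (conditional) association summary
#'
#' Pools, over genome-wide significant replicates, the fraction whose
#' conditional scan still contains a genome-wide significant common variant
#' and the fraction with no residual association at `alpha = 0.05`.
#'
#' @param replicates Replicate records from [run_grid()].
#' @return One-row data frame with the two proportions, their binomial
#'   standard errors and the number of conditioned replicates.
#' @export
secondary_summary <- function(replicates) {
  d <- replicates[replicates$gw_significant & !is.na(replicates$cond_gw), ]
  n <- nrow(d)
  p_gw <- mean(d$cond_gw)
  p_none <- mean(d$cond_none_05)
  data.frame(n = n,
             prop_secondary_gw = p_gw, se_secondary_gw = binom_se(p_gw, n),
             prop_no_residual_05 = p_none,
             se_no_residual_05 = binom_se(p_none, n))
}

#' Risk-allele-frequency summary of top synthetic hits
#'
#' Over genome-wide significant replicates: the median risk-allele
#' frequency of the top common hit (the frequency, in the pooled cohort, of
#' whichever allele carries the higher disease probability), the fraction
#' of hits with RAF above 0.25, and the fraction whose risk allele is the
#' ancestral one.
#'
#' @param replicates Replicate records from [run_grid()].
#' @return One-row data frame.
#' @export
raf_summary <- function(replicates) {
  d <- replicates[replicates$gw_significant & !is.na(replicates$raf), ]
  n <- nrow(d)
  p25 <- mean(d$raf > 0.25)
  panc <- mean(d$risk_allele == "ancestral")
  data.frame(n = n,
             median_raf = median(d$raf),
             prop_raf_gt_25 = p25, se_raf_gt_25 = binom_se(p25, n),
             prop_risk_ancestral = panc,
             se_risk_ancestral = binom_se(panc, n))
}

#' Proportion significant stratified by disease class
#'
#' Bins replicates by disease-class size and tabulates the proportion of
#' genome-wide significant simulations per (bin, number of causal sites).
#'
#' @param replicates Replicate records from [run_grid()].
#' @param breaks Disease-class bin boundaries.
#' @return Data frame with `bin`, `n_causal`, `n`, `prop_gw` and `se`;
#'   empty combinations are absent.
#' @export
disease_class_stratified <- function(replicates,
                                     breaks = c(0, 0.02, 0.04, 0.07, 0.12, 1)) {
  bin <- cut(replicates$disease_class, breaks = breaks, include.lowest = TRUE)
  sp <- split(replicates, list(bin = bin, k = replicates$n_causal), drop = TRUE)
  rows <- lapply(sp, function(d) {
    p <- mean(d$gw_significant)
    data.frame(bin = as.character(cut(d$disease_class[1], breaks = breaks,
                                      include.lowest = TRUE)),
               bin_mid = mean(range(d$disease_class)),
               n_causal = d$n_causal[1], n = nrow(d),
               prop_gw = p, se = binom_se(p, nrow(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$bin, out$n_causal), ]
}

#' Distance experiment: how far can a causal site act?
#'
#' Simulates a large region with uniform recombination (expressed as a
#' per-bp crossover rate mapped onto 500-bp fragments), nine rare causal
#' variants by default, and measures — for every genome-wide significant
#' replicate — the one-log-drop distance of [one_log_drop_distance()].
#'
#' @param replicates Number of replicates to run.
#' @param seed Master seed.
#' @param region_length Region size in bp. Default 10 Mb.
#' @param recomb_per_bp Per-meiosis crossover rate per bp. Default 1e-8
#'   (1 cM/Mb).
#' @param n_causal,grr,phi,n_per_arm Disease-model and cohort settings.
#' @param n_haplotypes,fragment_length Panel settings.
#' @param site_prefilter_maf Panel-MAF floor below which non-causal sites
#'   are not materialised in the cohort (memory guard for large regions).
#' @return List: `replicates` (per-replicate record incl. `distance`),
#'   `summary` (median distance, fraction below 2 Mb, fraction at least
#'   9 Mb, counts).
#' @export
distance_experiment <- function(replicates, seed = NULL,
                                region_length = 1e7, recomb_per_bp = 1e-8,
                                n_causal = 9, grr = 4, phi = 0.01,
                                n_per_arm = 2000,
                                n_haplotypes = 10000, fragment_length = 500,
                                site_prefilter_maf = 0.04) {
  params <- sim_params(n_haplotypes = n_haplotypes,
                       region_length = region_length,
                       fragment_length = fragment_length,
                       recomb_between_fragments = recomb_per_bp * fragment_length)
  dspec <- disease_spec(phi = phi, grr = grr, n_causal = n_causal)
  seeds <- derive_seeds(seed, replicates)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rec <- run_replicate(params, dspec, n_per_arm, seed = seeds[[r]],
                         conditional = FALSE,
                         site_prefilter_maf = site_prefilter_maf,
                         keep_objects = TRUE)
    dist <- NA_real_
    if (rec$gw_significant) {
      drop <- one_log_drop_distance(attr(rec, "cohort"), rec$top_site,
                                    attr(rec, "causal"))
      dist <- drop$distance
    }
    attr(rec, "panel") <- attr(rec, "causal") <- attr(rec, "cohort") <- NULL
    rec$distance <- dist
    rows[[r]] <- rec
  }
  reps <- do.call(rbind, rows)
  sig <- reps[reps$gw_significant, ]
  have <- sig[!is.na(sig$distance), ]
  summary <- data.frame(n_replicates = nrow(reps),
                        n_significant = nrow(sig),
                        n_with_distance = nrow(have),
                        median_distance = if (nrow(have)) median(have$distance)
                                          else NA_real_,
                        prop_lt_2mb = if (nrow(have)) mean(have$distance < 2e6)
                                      else NA_real_,
                        prop_ge_9mb = if (nrow(have)) mean(have$distance >= 9e6)
                                      else NA_real_)
  list(replicates = reps, summary = summary)
}
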