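# Shared fixtures: small, fast parameter sets and hand-built objects.

# A small panel configuration: theta = 4*Ne*mu*L = 40 as in the full-size
# default, so site counts are comparable, but with far fewer haplotypes.
small_params <- function(n_haplotypes = 400, recomb = 0, ...) {
  sim_params(n_haplotypes = n_haplotypes,
             recomb_between_fragments = recomb, ...)
}

# Build a hap_panel by hand from a 0/1 matrix (rows = haplotypes).
panel_from_matrix <- function(m, positions = NULL, fragment = NULL,
                              region_length = 1000) {
  if (is.null(positions)) positions <- seq(0.5, by = 1, length.out = ncol(m))
  if (is.null(fragment)) fragment <- rep(0L, ncol(m))
  structure(list(n_hap = nrow(m),
                 positions = positions,
                 fragment = as.integer(fragment),
                 carriers = lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L)),
                 freq = colMeans(m),
                 n_rec_events = 0, n_coal_events = nrow(m) - 1,
                 params = sim_params(n_haplotypes = max(4L, nrow(m) + nrow(m) %% 2L),
                                     region_length = region_length,
                                     fragment_length = region_length,
                                     n_fragments = 1L),
                 seed = NULL),
            class = "hap_panel")
}

# Build a cohort directly from a genotype matrix and status vector,
# bypassing ascertainment (for scan unit tests with controlled tables).
cohort_from_genotypes <- function(g, status, positions = NULL,
                                  fragment = NULL) {
  g <- as.matrix(g)
  if (is.null(positions)) positions <- seq(0.5, by = 1, length.out = ncol(g))
  if (is.null(fragment)) fragment <- rep(0L, ncol(g))
  structure(list(h1 = seq_len(nrow(g)), h2 = seq_len(nrow(g)),
                 status = as.logical(status),
                 genotypes = g,
                 site_index = seq_len(ncol(g)),
                 positions = positions,
                 fragment = as.integer(fragment),
                 n_cases = sum(status), n_controls = sum(!status),
                 n_drawn = nrow(g)),
            class = "cohort")
}

# Genotype vector realising exact 2x3 genotype-by-status counts.
genotypes_from_table <- function(case_counts, ctrl_counts) {
  g <- c(rep(0:2, times = case_counts), rep(0:2, times = ctrl_counts))
  status <- rep(c(TRUE, FALSE), times = c(sum(case_counts), sum(ctrl_counts)))
  list(g = g, status = status)
}

empty_causal <- function() {
  structure(list(sites = integer(0), freq = numeric(0)), class = "causal_set")
}

causal_from_sites <- function(panel, sites) {
  structure(list(sites = as.integer(sites), freq = panel$freq[sites]),
            class = "causal_set")
}
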