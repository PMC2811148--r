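test_that("disease_spec validates and derives gamma/grr consistently", {
  ds <- disease_spec(phi = 0.01, grr = 4)
  expect_equal(ds$gamma, 0.04)
  expect_equal(ds$grr, ds$gamma / ds$phi)
  expect_error(disease_spec(phi = 0.2, gamma = 0.1))   # gamma < phi
  expect_error(disease_spec(phi = 0.3, grr = 6))       # gamma > 1
})

test_that("causal selection respects the frequency window", {
  panel <- simulate_panel(small_params(), seed = 21)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 3)
  causal <- select_causal_sites(panel, ds, seed = 1)
  expect_length(causal$sites, 3)
  expect_false(anyDuplicated(causal$sites) > 0)
  expect_true(all(causal$freq >= 0.005 & causal$freq <= 0.02))
})

test_that("k = 0 gives an empty causal set; exactly-k panels are deterministic", {
  panel <- simulate_panel(small_params(), seed = 22)
  expect_length(select_causal_sites(panel, disease_spec(phi = 0.01, grr = 4,
                                                        n_causal = 0))$sites, 0)
  # brute-force oracle: the eligible set itself
  eligible <- which(panel$freq >= 0.005 & panel$freq <= 0.02)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = length(eligible))
  causal <- select_causal_sites(panel, ds, seed = 5)
  expect_identical(causal$sites, eligible)
})

test_that("insufficient eligible sites signals a genealogy redraw", {
  panel <- panel_from_matrix(cbind(c(1, 1, 0, 0), c(0, 1, 1, 1)))  # freqs .5 .75
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 1)
  expect_error(select_causal_sites(panel, ds), class = "synthassoc_redraw")
})

test_that("disease class size equals the brute-force carrier union", {
  panel <- simulate_panel(small_params(), seed = 23)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 5)
  causal <- select_causal_sites(panel, ds, seed = 2)
  expect_identical(disease_class_size(panel, empty_causal()), 0)
  one <- causal_from_sites(panel, causal$sites[1])
  expect_equal(disease_class_size(panel, one), panel$freq[causal$sites[1]])
  m <- as.matrix(panel)[, causal$sites, drop = FALSE]
  expect_equal(disease_class_size(panel, causal),
               mean(rowSums(m) >= 1))
})

test_that("deterministic penetrance separates carriers and non-carriers", {
  panel <- simulate_panel(small_params(), seed = 24)
  ds <- disease_spec(phi = 0, gamma = 1, n_causal = 5)
  causal <- select_causal_sites(panel, ds, seed = 3)
  coh <- sample_cohort(panel, causal, ds, 50, seed = 4)
  carrier_h <- carrier_haplotypes(panel, causal)
  carrier_ind <- carrier_h[coh$h1] | carrier_h[coh$h2]
  expect_true(all(carrier_ind[coh$status]))
  expect_false(any(carrier_ind[!coh$status]))
  expect_equal(coh$n_cases, 50)
  expect_equal(coh$n_controls, 50)
})

test_that("carrier enrichment among cases matches the Bayes-rule oracle", {
  panel <- simulate_panel(sim_params(n_haplotypes = 2000), seed = 25)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 9)
  causal <- select_causal_sites(panel, ds, seed = 5)
  coh <- sample_cohort(panel, causal, ds, 2000, seed = 6)
  d <- disease_class_size(panel, causal)
  q <- 1 - (1 - d)^2
  p_carrier_case <- q * ds$gamma / (q * ds$gamma + (1 - q) * ds$phi)
  p_carrier_ctrl <- q * (1 - ds$gamma) /
    (q * (1 - ds$gamma) + (1 - q) * (1 - ds$phi))
  carrier_h <- carrier_haplotypes(panel, causal)
  carrier_ind <- carrier_h[coh$h1] | carrier_h[coh$h2]
  obs_case <- mean(carrier_ind[coh$status])
  obs_ctrl <- mean(carrier_ind[!coh$status])
  expect_gt(obs_case, obs_ctrl)
  expect_lt(abs(obs_case - p_carrier_case),
            3 * sqrt(p_carrier_case * (1 - p_carrier_case) / 2000))
  expect_lt(abs(obs_ctrl - p_carrier_ctrl),
            3 * sqrt(p_carrier_ctrl * (1 - p_carrier_ctrl) / 2000))
})

test_that("genotypes are additive codes of the drawn haplotype pair", {
  panel <- simulate_panel(small_params(n_haplotypes = 100), seed = 26)
  ds <- disease_spec(phi = 0.05, grr = 2, n_causal = 1)
  causal <- select_causal_sites(panel, ds, seed = 7)
  coh <- sample_cohort(panel, causal, ds, 30, seed = 8)
  m <- as.matrix(panel)
  expect_identical(coh$genotypes, m[coh$h1, ] + m[coh$h2, ])
  expect_true(all(coh$genotypes %in% 0:2))
})

test_that("null-site genotype means track 2x the panel frequency", {
  panel <- simulate_panel(sim_params(n_haplotypes = 2000), seed = 27)
  ds <- disease_spec(phi = 0.05, gamma = 0.05, n_causal = 1)  # no effect
  causal <- select_causal_sites(panel, ds, seed = 9)
  coh <- sample_cohort(panel, causal, ds, 1500, seed = 10)
  fbar <- colMeans(coh$genotypes) / 2
  common <- panel$freq > 0.1 & panel$freq < 0.9
  se <- sqrt(panel$freq[common] * (1 - panel$freq[common]) / (2 * 3000))
  expect_true(all(abs(fbar[common] - panel$freq[common]) < 5 * se))
})

test_that("unreachable quotas abort with an infeasibility signal", {
  panel <- simulate_panel(small_params(), seed = 28)
  ds <- disease_spec(phi = 0, gamma = 1, n_causal = 0)  # nobody can be a case
  expect_error(sample_cohort(panel, empty_causal(), ds, 10, seed = 11,
                             max_draw = 5e4),
               class = "synthassoc_infeasible")
})
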