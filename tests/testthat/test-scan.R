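test_that("masking arithmetic matches brute-force set operations", {
  panel <- simulate_panel(small_params(), seed = 31)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 3)
  causal <- select_causal_sites(panel, ds, seed = 1)
  coh <- sample_cohort(panel, causal, ds, 300, seed = 2)
  common <- eligible_common_sites(panel, causal, coh)
  # oracle: panel MAF >= 0.05 minus causal sites
  maf <- pmin(panel$freq, 1 - panel$freq)
  expect_setequal(common, setdiff(which(maf >= 0.05), causal$sites))
  masked <- attr(common, "masked")
  expect_setequal(masked$site, setdiff(seq_len(n_sites(panel)), common))
  expect_true(all(masked$reason[masked$site %in% causal$sites] == "causal"))
})

test_that("fragment exclusion masks common sites sharing a causal fragment", {
  m <- cbind(rep(c(1, 0), c(2, 98)),           # rare site, fragment 0
             rep(c(1, 0), c(30, 70)),          # common, fragment 0 -> masked
             rep(c(0, 1, 0), c(5, 30, 65)))    # common, fragment 1 -> kept
  panel <- panel_from_matrix(m, positions = c(10, 400, 600),
                             fragment = c(0L, 0L, 1L))
  causal <- causal_from_sites(panel, 1L)
  g <- genotypes_from_table(c(10, 5, 1), c(10, 5, 1))
  coh <- cohort_from_genotypes(cbind(g$g, g$g, g$g), g$status,
                               positions = panel$positions,
                               fragment = panel$fragment)
  kept <- eligible_common_sites(panel, causal, coh, fragment_exclusion = TRUE)
  expect_identical(as.integer(kept), 3L)
  reasons <- attr(kept, "masked")
  expect_identical(reasons$reason[reasons$site == 2], "same_fragment_as_causal")
  # with exclusion off the same-fragment common site is tested
  kept2 <- eligible_common_sites(panel, causal, coh, fragment_exclusion = FALSE)
  expect_setequal(kept2, c(2L, 3L))
})

test_that("a site with identical case/control distributions is null", {
  g <- genotypes_from_table(c(500, 90, 10), c(500, 90, 10))
  coh <- cohort_from_genotypes(matrix(g$g), g$status)
  tab <- logistic_scan(coh, 1L)
  expect_lt(abs(tab$beta), 1e-8)
  expect_equal(tab$or, 1, tolerance = 1e-8)
  expect_gt(tab$p, 0.999)
})

test_that("scan p-values agree with the Cochran-Armitage trend oracle", {
  # toy table: cases 400/150/50, controls 500/90/10 by genotype 0/1/2
  g <- genotypes_from_table(c(400, 150, 50), c(500, 90, 10))
  coh <- cohort_from_genotypes(matrix(g$g), g$status)
  tab <- logistic_scan(coh, 1L)
  counts_case <- c(400, 150, 50)
  counts_tot <- counts_case + c(500, 90, 10)
  trend <- prop.trend.test(counts_case, counts_tot, score = 0:2)
  expect_lt(abs(log10(tab$p) - log10(trend$p.value)), 1)
})

test_that("fits agree with glm() and OR equals exp(beta) exactly", {
  panel <- simulate_panel(small_params(), seed = 32)
  ds <- disease_spec(phi = 0.01, grr = 4, n_causal = 3)
  causal <- select_causal_sites(panel, ds, seed = 3)
  coh <- sample_cohort(panel, causal, ds, 500, seed = 4)
  common <- eligible_common_sites(panel, causal, coh)
  tab <- logistic_scan(coh, common)
  expect_identical(tab$or, exp(tab$beta))
  for (s in common[seq(1, length(common), length.out = 4)]) {
    gcol <- coh$genotypes[, match(s, coh$site_index)]
    sm <- summary(glm(coh$status ~ gcol, family = binomial))$coefficients
    row <- tab[tab$site == s, ]
    expect_equal(row$beta, sm[2, 1], tolerance = 1e-6)
    expect_equal(row$se, sm[2, 2], tolerance = 1e-6)
    expect_equal(row$p, sm[2, 4], tolerance = 1e-5)
  }
  # conditional fit against glm with the covariate included
  cov <- coh$genotypes[, match(common[1], coh$site_index)]
  ctab <- conditional_scan(coh, common, common[1])
  s2 <- ctab$site[which.min(ctab$p)]
  g2 <- coh$genotypes[, match(s2, coh$site_index)]
  sm2 <- summary(glm(coh$status ~ g2 + cov, family = binomial))$coefficients
  expect_equal(ctab$beta[ctab$site == s2], sm2[2, 1], tolerance = 1e-6)
  expect_equal(ctab$p[ctab$site == s2], sm2[2, 4], tolerance = 1e-5)
})

test_that("relabelling alleles flips beta and inverts the OR, p unchanged", {
  g <- genotypes_from_table(c(400, 150, 50), c(500, 90, 10))
  coh1 <- cohort_from_genotypes(matrix(g$g), g$status)
  coh2 <- cohort_from_genotypes(matrix(2L - g$g), g$status)
  t1 <- logistic_scan(coh1, 1L)
  t2 <- logistic_scan(coh2, 1L)
  expect_equal(t1$p, t2$p, tolerance = 1e-9)
  expect_equal(t1$beta, -t2$beta, tolerance = 1e-9)
  expect_equal(t1$or, 1 / t2$or, tolerance = 1e-9)
  expect_false(identical(t1$risk_allele, t2$risk_allele))
})

test_that("likelihood-ratio test is available and close to Wald here", {
  g <- genotypes_from_table(c(400, 150, 50), c(500, 90, 10))
  coh <- cohort_from_genotypes(matrix(g$g), g$status)
  pw <- logistic_scan(coh, 1L, test = "wald")$p
  pl <- logistic_scan(coh, 1L, test = "lrt")$p
  fit1 <- glm(g$status ~ g$g, family = binomial)
  lrt_oracle <- anova(glm(g$status ~ 1, family = binomial), fit1, test = "LRT")
  expect_equal(pl, lrt_oracle$`Pr(>Chi)`[2], tolerance = 1e-6)
  expect_lt(abs(log10(pw) - log10(pl)), 1.5)
})

test_that("conditioning on a duplicate site is flagged collinear, not fatal", {
  g <- genotypes_from_table(c(400, 150, 50), c(500, 90, 10))
  coh <- cohort_from_genotypes(cbind(g$g, g$g), g$status)
  ctab <- conditional_scan(coh, c(1L, 2L), 2L)  # tests site 1 given its copy
  expect_true(is.na(ctab$p[1]))
  expect_true(ctab$fit_status[1] %in% c("singular", "separated"))
})

test_that("disjoint signals survive conditioning; a sole tag does not", {
  # two independent binary risk factors, both associated with status
  set.seed(77)
  n <- 6000
  x1 <- rbinom(n, 2, 0.15)
  x2 <- rbinom(n, 2, 0.15)
  eta <- -2.5 + 0.55 * x1 + 0.55 * x2
  y <- runif(n) < plogis(eta)
  coh <- cohort_from_genotypes(cbind(x1, x2), y)
  p_x2 <- logistic_scan(coh, 2L)$p
  p_x2_cond <- conditional_scan(coh, c(1L, 2L), 1L)$p
  expect_lt(abs(log10(p_x2_cond) - log10(p_x2)), 1)  # barely moves
  # single signal: conditioning on itself (via a high-LD proxy) removes it
  x1b <- x1; flip <- sample(n, 30)
  x1b[flip] <- pmin(2, pmax(0, x1b[flip] + sample(c(-1, 1), 30, TRUE)))
  coh2 <- cohort_from_genotypes(cbind(x1, x1b), y)
  p_proxy <- logistic_scan(coh2, 2L)$p
  p_proxy_cond <- conditional_scan(coh2, c(1L, 2L), 1L)$p
  expect_lt(p_proxy, 1e-8)
  expect_gt(p_proxy_cond, 1e-3)
})

test_that("one-log-drop distance identifies the contributing causal site", {
  p <- sim_params(n_haplotypes = 4000)
  ds <- disease_spec(phi = 0.01, grr = 6, n_causal = 1)
  found <- FALSE
  for (s in 1:15) {
    rec <- run_replicate(p, ds, 3000, seed = 800 + s, keep_objects = TRUE,
                         conditional = FALSE)
    if (!rec$gw_significant) next
    cohort <- attr(rec, "cohort"); causal <- attr(rec, "causal")
    drop <- one_log_drop_distance(cohort, rec$top_site, causal)
    if (length(drop$contributing)) {
      expect_identical(drop$contributing, causal$sites)
      expect_equal(drop$distance,
                   abs(cohort$positions[match(causal$sites, cohort$site_index)] -
                       rec$top_pos))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("an uncorrelated covariate cannot produce a one-log drop", {
  set.seed(88)
  n <- 6000
  x <- rbinom(n, 2, 0.2)
  y <- runif(n) < plogis(-2 + 0.5 * x)
  z <- rbinom(n, 2, 0.01)              # independent rare site
  coh <- cohort_from_genotypes(cbind(x, z), y)
  causal <- structure(list(sites = 2L, freq = 0.01), class = "causal_set")
  drop <- one_log_drop_distance(coh, 1L, causal)
  expect_length(drop$contributing, 0)
  expect_true(is.na(drop$distance))
})

test_that("an empty eligible set yields an empty table, not an error", {
  g <- genotypes_from_table(c(5, 1, 0), c(5, 1, 0))
  coh <- cohort_from_genotypes(matrix(g$g), g$status)
  tab <- logistic_scan(coh, integer(0))
  expect_s3_class(tab, "assoc_table")
  expect_identical(nrow(tab), 0L)
  expect_null(top_hit(tab))
})
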