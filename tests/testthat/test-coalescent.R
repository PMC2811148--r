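test_that("zero mutation rate gives a degenerate empty panel with a signal", {
  p <- sim_params(n_haplotypes = 10, mutation_rate = 0,
                  region_length = 1000, n_fragments = 2)
  expect_warning(panel <- simulate_panel(p, seed = 1),
                 class = "synthassoc_degenerate_panel")
  expect_equal(n_sites(panel), 0L)
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(n_haplotypes = 3), "n_haplotypes")
  expect_error(sim_params(n_haplotypes = 7), "n_haplotypes")
  expect_error(sim_params(region_length = 1000, fragment_length = 300,
                          n_fragments = 3), "region_length")
  expect_error(sim_params(mutation_rate = -1), "mutation_rate")
})

test_that("segregating-site count matches Watterson's expectation", {
  # E[S] = 4 Ne mu L * sum_{i=1}^{n-1} 1/i under the neutral coalescent
  p <- sim_params()  # defaults: n = 10,000, Ne = 1e4, mu = 1e-8, L = 1e5
  s_counts <- vapply(1:50, function(i) n_sites(simulate_panel(p, seed = i)),
                     numeric(1))
  expected <- 4 * p$effective_pop_size * p$mutation_rate * p$region_length *
    sum(1 / seq_len(p$n_haplotypes - 1))
  se <- sd(s_counts) / sqrt(length(s_counts))
  expect_lt(abs(mean(s_counts) - expected), 3 * se)
})

test_that("panel structure invariants hold", {
  panel <- simulate_panel(small_params(), seed = 3)
  expect_gt(n_sites(panel), 0)
  expect_false(is.unsorted(panel$positions, strictly = TRUE))
  expect_true(all(panel$freq > 0 & panel$freq < 1))
  m <- as.matrix(panel)
  expect_identical(dim(m), c(panel$n_hap, n_sites(panel)))
  expect_equal(colMeans(m), panel$freq)
  expect_true(all(panel$fragment >= 0 &
                  panel$fragment < panel$params$n_fragments))
  expect_true(all(floor(panel$positions / panel$params$fragment_length) ==
                  panel$fragment))
})

test_that("no recombination implies zero four-gamete violations", {
  panel <- simulate_panel(sim_params(), seed = 11)
  expect_identical(four_gamete_violations(panel), 0L)
})

test_that("recombination produces four-gamete violations across fragments only", {
  panel <- simulate_panel(small_params(recomb = 5e-4), seed = 5)
  expect_gt(panel$n_rec_events, 0)
  # within any single fragment the infinite-sites tree is intact
  for (f in unique(panel$fragment)) {
    in_f <- which(panel$fragment == f)
    if (length(in_f) >= 2)
      expect_identical(four_gamete_violations(panel, in_f), 0L)
  }
  expect_gt(four_gamete_violations(panel), 0L)
})

test_that("a fixed seed reproduces the panel bit for bit", {
  p <- small_params(recomb = 1e-4)
  a <- simulate_panel(p, seed = 99)
  b <- simulate_panel(p, seed = 99)
  d <- simulate_panel(p, seed = 100)
  expect_identical(a$positions, b$positions)
  expect_identical(a$carriers, b$carriers)
  expect_false(identical(a$positions, d$positions))
})

test_that("site-frequency spectrum is monotone decreasing on average", {
  p <- sim_params(n_haplotypes = 1000)
  counts <- sapply(1:30, function(i) {
    panel <- simulate_panel(p, seed = 400 + i)
    k <- round(panel$freq * panel$n_hap)
    c(sum(k == 1), sum(k == 2), sum(k == 3), sum(k == 4))
  })
  avg <- rowMeans(counts)
  expect_true(all(diff(avg) < 0))
})

test_that("linked pair at rate 0 behaves as a single tree", {
  panel <- simulate_linked_pair(400, 0, sim_params(fragment_length = 5000),
                                seed = 7)
  expect_identical(four_gamete_violations(panel), 0L)
  expect_setequal(unique(panel$fragment), c(0L, 1L))
})

test_that("very large recombination approaches cross-locus independence", {
  # oracle: mean r^2 between sites of two fully independent panels
  prm <- sim_params(n_haplotypes = 200, fragment_length = 20000)
  r2_linked <- c(); r2_indep <- c()
  for (i in 1:40) {
    pan <- simulate_linked_pair(200, 0.5, prm, seed = 1000 + i)
    a <- which(pan$fragment == 0L); b <- which(pan$fragment == 1L)
    if (length(a) && length(b)) {
      m <- as.matrix(pan)
      r2_linked <- c(r2_linked,
                     synthassoc:::cross_r2(m[, a, drop = FALSE],
                                           m[, b, drop = FALSE]))
    }
    p1 <- suppressWarnings(simulate_panel(
      sim_params(n_haplotypes = 200, region_length = 20000,
                 fragment_length = 20000, n_fragments = 1), seed = 5000 + i))
    p2 <- suppressWarnings(simulate_panel(
      sim_params(n_haplotypes = 200, region_length = 20000,
                 fragment_length = 20000, n_fragments = 1), seed = 7000 + i))
    if (n_sites(p1) && n_sites(p2))
      r2_indep <- c(r2_indep, synthassoc:::cross_r2(as.matrix(p1),
                                                    as.matrix(p2)))
  }
  se <- sqrt(var(r2_linked) / length(r2_linked) +
             var(r2_indep) / length(r2_indep))
  expect_lt(abs(mean(r2_linked) - mean(r2_indep)), 4 * se)
})
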