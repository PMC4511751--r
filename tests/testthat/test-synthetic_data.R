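test_that("coalescent generator matches Watterson and pairwise expectations", {
  theta <- 5; n <- 10; reps <- 1500
  a1 <- sum(1 / seq_len(n - 1))
  set.seed(20)
  seeds <- sample.int(1e6, reps)
  S <- numeric(reps); pi_L <- numeric(reps)
  for (i in seq_len(reps)) {
    aln <- simulate_coalescent_alignment(n, theta, 150, seed = seeds[i])
    S[i] <- segregating_sites(aln)
    pi_L[i] <- nucleotide_diversity(aln) * aln$length
  }
  # E[S] = theta * a_{n-1}; E[pi * L] = theta (Monte-Carlo, 3 SE bands)
  expect_lt(abs(mean(S) - theta * a1), 3 * stats::sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi_L) - theta), 3 * stats::sd(pi_L) / sqrt(reps))
  # and the sample-mean Watterson estimator is unbiased for theta
  th_hat <- S / a1
  expect_lt(abs(mean(th_hat) - theta), 3 * stats::sd(th_hat) / sqrt(reps))
})

test_that("coalescent generator honours theta = 0 and the seed contract", {
  aln0 <- simulate_coalescent_alignment(6, 0, 100, seed = 1)
  expect_equal(segregating_sites(aln0), 0L)
  a <- simulate_coalescent_alignment(6, 3, 100, seed = 5)
  b <- simulate_coalescent_alignment(6, 3, 100, seed = 5)
  c_ <- simulate_coalescent_alignment(6, 3, 100, seed = 6)
  expect_identical(alignment_sequences(a), alignment_sequences(b))
  expect_false(identical(alignment_sequences(a), alignment_sequences(c_)))
})

test_that("island samples recover the finite-island F_ST expectation", {
  d <- 10; nm <- 1; reps <- 60
  expected <- 1 / (1 + 4 * nm * (d / (d - 1))^2)
  set.seed(30)
  seeds <- sample.int(1e6, reps)
  fst <- vapply(seq_len(reps), function(i) {
    sim <- simulate_island_samples(d, 4, nm, theta = 5, length_bp = 5000,
                                   seed = seeds[i])
    # mean pairwise F_ST over three sampled deme pairs
    prs <- list(c("deme1", "deme2"), c("deme3", "deme4"), c("deme5", "deme6"))
    mean(vapply(prs, function(p)
      pairwise_fst(sim$alignment, sim$map, p[1], p[2])$fst, numeric(1)),
      na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fst) - expected) / expected, 0.2)
})

test_that("island samples hit the panmixia and deep-divergence limits", {
  set.seed(31)
  seeds <- sample.int(1e6, 20)
  fst_hi <- vapply(seeds, function(s) {
    sim <- simulate_island_samples(4, 4, nm = 100, theta = 5,
                                   length_bp = 5000, seed = s)
    pairwise_fst(sim$alignment, sim$map, "deme1", "deme2")$fst
  }, numeric(1))
  expect_lt(abs(mean(fst_hi, na.rm = TRUE)), 0.05)

  sim0 <- simulate_island_samples(3, 8, nm = 0, theta = 2, length_bp = 2000,
                                  seed = 2, t_split = 20)
  expect_gt(pairwise_fst(sim0$alignment, sim0$map, "deme1", "deme2")$fst, 0.9)
  expect_error(simulate_island_samples(3, 8, nm = 0, theta = 2,
                                       length_bp = 2000, seed = 2),
               "t_split")
})

test_that("star-phylogeny generator matches its Poisson mean", {
  aln0 <- generate_star_haplotypes(5, 1000, 1e-9, 0, seed = 1)
  expect_equal(length(unique(alignment_sequences(aln0))), 1L)

  # same total Poisson rate n*L*mu*t as the 10-kbp headline case, at a
  # smaller alignment so many replicates stay cheap
  n <- 23; L <- 100; mu <- 1e-7; t <- 13024
  set.seed(40)
  seeds <- sample.int(1e6, 1200)
  nmut <- vapply(seeds, function(s) {
    aln <- generate_star_haplotypes(n, L, mu, t, seed = s)
    segregating_sites(aln)
  }, integer(1))
  lambda <- n * L * mu * t
  expect_lt(abs(mean(nmut) - lambda) / lambda, 0.1)
  # zero-mutation fraction near alpha = 0.05 at the bound age
  expect_lt(abs(mean(nmut == 0) - 0.05), 0.02)
})

test_that("preference and titration fixtures sit on their model curves", {
  pd <- generate_preference_trials(100, 2, noise_sd = 0, seed = 1)
  expect_equal(nrow(pd), 30L)  # 5 concentrations x 6 trials
  expect_setequal(unique(pd$concentration), c(1, 10, 100, 250, 1000))
  expect_equal(pd$ratio[pd$concentration == 100][1], 0.25)
  expect_equal(pd$ratio, 0.5 / (1 + (pd$concentration / 100)^2))

  td <- generate_titration_curves(0, 2, 50, 1.5, concentrations = c(1, 50, 1000),
                                  noise_sd = 0, seed = 1)
  expect_equal(sum(td$concentration == td$concentration[1]), 3L)
  expect_equal(td$response[td$concentration == 50][1], 1)  # midpoint
  hi <- generate_titration_curves(0, 2, 50, 1.5, concentrations = 1e8,
                                  noise_sd = 0)
  expect_equal(hi$response[1], 2, tolerance = 1e-6)

  p1 <- generate_preference_trials(100, 2, noise_sd = 0.05, seed = 9)
  p2 <- generate_preference_trials(100, 2, noise_sd = 0.05, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$ratio >= 0 & p1$ratio <= 1))
})
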