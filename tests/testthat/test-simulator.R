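test_that("parameter validation names the violated constraint", {
  expect_error(sim_params(p = 0), "strictly in \\(0, 1\\)")
  expect_error(sim_params(p = 0.3, beta2 = -0.1), "non-negative")
  expect_error(sim_params(p = 0.5, beta1 = 1, sigma2_g = 0.1),
               "2\\*p\\*\\(1-p\\)\\*beta1")
  expect_error(sim_params(p = 0.5, beta2 = 0.8, sigma2_g = 0.5),
               "exceeds 1")
})

test_that("degenerate all-noise cohort has unit variance and no twin correlation", {
  prm <- sim_params(p = 0.3, n_pairs = 50000, seed = 11)
  ch <- simulate_twin_cohort(prm)
  expect_equal(var(ch$yA), 1, tolerance = 0.03)
  expect_lt(abs(cor(ch$yA, ch$yB)), 3 / sqrt(prm$n_pairs))
  expect_true(all(ch$G %in% 0:2))
})

test_that("twin correlation recovers the heritability when beta2 = 0", {
  # the parameter set of the false-discovery study: h2 = 0.5, p = 0.1
  prm <- sim_params(p = 0.1, beta1 = 0.1, sigma2_g = 0.5, n_pairs = 100000,
                    seed = 12)
  ch <- simulate_twin_cohort(prm)
  expect_equal(cor(ch$yA, ch$yB), 0.5, tolerance = 0.02)
  expect_equal(var(ch$yA), 1, tolerance = 0.03)
})

test_that("pair-difference variance matches the closed form and a brute-force oracle", {
  p <- 0.25; beta1 <- 0.1; beta2 <- 0.15; h2 <- 0.4
  prm <- sim_params(p = p, beta1 = beta1, beta2 = beta2, sigma2_g = h2,
                    n_pairs = 100000, seed = 13)
  ch <- simulate_twin_cohort(prm)
  # var(yA - yB) = 2 * (beta2 * E[G] + sigma2_e), E[G] = 2p
  closed <- 2 * (beta2 * 2 * p + prm$sigma2_e)
  expect_equal(var(ch$yA - ch$yB), closed, tolerance = 0.03)
  set.seed(14)
  bf <- brute_force_twins(100000, p, beta1, beta2, h2)
  expect_equal(var(ch$yA - ch$yB), var(bf$yA - bf$yB), tolerance = 0.03)
})

test_that("variance is conserved across parameter sets (property)", {
  grid <- list(c(p = 0.1, b1 = 0, b2 = 0.3, h2 = 0.2),
               c(p = 0.5, b1 = 0.2, b2 = 0.05, h2 = 0.7),
               c(p = 0.3, b1 = 0.1, b2 = 0, h2 = 0.9))
  for (g in grid) {
    prm <- sim_params(p = g["p"], beta1 = g["b1"], beta2 = g["b2"],
                      sigma2_g = g["h2"], n_pairs = 60000, seed = 15)
    ch <- simulate_twin_cohort(prm)
    mc_se <- sqrt(2 / prm$n_pairs)  # var of a unit-variance normal sample
    expect_lt(abs(var(ch$yA) - 1), 3 * mc_se + 0.01)
  }
})

test_that("identical seed gives bit-identical cohorts; different seeds differ", {
  prm <- sim_params(p = 0.3, sigma2_g = 0.5, n_pairs = 200, seed = 16)
  a <- simulate_twin_cohort(prm); b <- simulate_twin_cohort(prm)
  expect_identical(a$yA, b$yA); expect_identical(a$G, b$G)
  prm2 <- prm; prm2$seed <- 17
  expect_false(identical(simulate_twin_cohort(prm2)$yA, a$yA))
})

test_that("population cohort recovers additive effect, conditional variance and EAF", {
  prm <- sim_params(p = 0.5, beta1 = 0.5, sigma2_g = 0.5,
                    n_individuals = 100000, seed = 18)
  pc <- simulate_population_cohort(prm)
  expect_equal(unname(coef(lm(pc$y ~ pc$G))[2]), 0.5, tolerance = 0.02)

  prm2 <- sim_params(p = 0.3, beta1 = 0.1, beta2 = 0.2, sigma2_g = 0.3,
                     n_individuals = 200000, seed = 19)
  pc2 <- simulate_population_cohort(prm2)
  # var(y | G = g) = (1 - 2p(1-p)beta1^2) - sigma2_v + beta2 * g
  base <- 1 - 2 * 0.3 * 0.7 * 0.01 - prm2$sigma2_v
  for (g in 0:2) {
    expect_equal(var(pc2$y[pc2$G == g]), base + 0.2 * g, tolerance = 0.05)
  }

  prm3 <- sim_params(p = 0.3, n_individuals = 500000, seed = 20)
  pc3 <- simulate_population_cohort(prm3)
  expect_equal(mean(pc3$G) / 2, 0.3, tolerance = 0.005)
})

test_that("tagged locus construction hits the target LD", {
  prm <- sim_params(p = 0.1, n_pairs = 200000, seed = 21)
  tl1 <- simulate_tagged_locus(prm, 1)
  expect_identical(tl1$G_causal, tl1$G_tag)
  tl0 <- simulate_tagged_locus(prm, 0)
  expect_lt(cor(tl0$G_causal, tl0$G_tag)^2, 1e-3)
  tl <- simulate_tagged_locus(prm, 0.5)
  # enumeration oracle: exact corr^2 from the four haplotype frequencies
  p <- 0.1; D <- sqrt(0.5) * p * (1 - p)
  f <- c(p^2 + D, p * (1 - p) - D, (1 - p) * p - D, (1 - p)^2 + D)
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  covh <- sum(f * a * b) - sum(f * a) * sum(f * b)
  exact <- covh^2 / (p * (1 - p))^2
  expect_equal(exact, 0.5, tolerance = 1e-12)
  expect_equal(tagged_locus_r2_exact(0.1, 0.5), 0.5, tolerance = 1e-12)
  expect_equal(cor(tl$G_causal, tl$G_tag)^2, 0.5, tolerance = 0.02)
  expect_equal(mean(tl$G_tag) / 2, 0.1, tolerance = 0.01)
})

test_that("covariate tables are reproducible, seed-sensitive and well scaled", {
  a <- simulate_covariates(10, seed = 22)
  b <- simulate_covariates(10, seed = 22)
  expect_identical(a, b)
  expect_equal(dim(a), c(10L, 12L))
  expect_false(identical(simulate_covariates(10, seed = 23), a))
  big <- simulate_covariates(100000, seed = 24)
  expect_equal(mean(big$PC3), 0, tolerance = 0.02)
  expect_equal(var(big$PC7), 1, tolerance = 0.03)
})
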