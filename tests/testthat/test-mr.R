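test_that("harmonization resolves all four allele orientations correctly", {
  exp_tab <- data.frame(snp = paste0("rs", 1:5), chr = 1, pos = 1:5 * 100,
                        A1 = c("A", "A", "A", "A", "A"),
                        A2 = c("G", "G", "G", "G", "C"),
                        beta = rep(0.1, 5), se = rep(0.01, 5),
                        eaf = rep(0.3, 5))
  out_tab <- data.frame(snp = paste0("rs", 1:5), chr = 1, pos = 1:5 * 100,
                        A1 = c("A", "G", "T", "C", "A"),   # direct, swap,
                        A2 = c("G", "A", "C", "T", "G"),   # flip, flip+swap,
                        beta = rep(0.2, 5), se = rep(0.02, 5), # mismatch
                        eaf = rep(0.3, 5))
  h <- mr_harmonize(exp_tab, out_tab)
  expect_equal(nrow(h), 4)  # the A/C-vs-A/G pair is dropped
  expect_equal(h$beta_out, c(0.2, -0.2, 0.2, -0.2))
  expect_equal(h$beta_exp, rep(0.1, 4))
})

test_that("ambiguous palindromic instruments are dropped, resolvable ones aligned", {
  exp_tab <- data.frame(snp = c("p1", "p2"), chr = 1, pos = c(10, 20),
                        A1 = "A", A2 = "T", beta = 0.1, se = 0.01,
                        eaf = c(0.2, 0.49))
  out_tab <- data.frame(snp = c("p1", "p2"), chr = 1, pos = c(10, 20),
                        A1 = "A", A2 = "T", beta = 0.3, se = 0.02,
                        eaf = c(0.8, 0.49))
  h <- mr_harmonize(exp_tab, out_tab)
  expect_equal(h$snp, "p1")          # frequency-resolvable, opposite side
  expect_equal(h$beta_out, -0.3)     # treated as swapped
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  set.seed(61)
  d <- simulate_mr_instruments(50, 0.5, se_scale = 0.05, seed = 62)
  got <- mr_ivw(d)
  oracle <- ivw_oracle(d$beta_exp, d$beta_out, d$se_out)
  expect_equal(got$beta, oracle$beta, tolerance = 1e-12)
  expect_equal(got$se, oracle$se, tolerance = 1e-12)
  expect_equal(got$Q_df, 49L)
  # invariance to simultaneous sign flip of one instrument
  d2 <- d; d2$beta_exp[3] <- -d2$beta_exp[3]; d2$beta_out[3] <- -d2$beta_out[3]
  expect_equal(mr_ivw(d2)$beta, got$beta, tolerance = 1e-12)
})

test_that("IVW handles single instruments, nulls and parameter recovery", {
  one <- data.frame(snp = "rs1", beta_exp = 0.2, se_exp = 0.01,
                    beta_out = 0.1, se_out = 0.05)
  w <- mr_ivw(one)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.25)
  null_d <- simulate_mr_instruments(30, 0, se_scale = 0.01, seed = 63)
  null_d$beta_out <- 0
  z <- mr_ivw(null_d)
  expect_equal(z$beta, 0)
  expect_equal(z$p, 1)
  est0 <- mr_ivw(simulate_mr_instruments(102, 0, se_scale = 0.01,
                                         seed = 64))
  expect_lt(abs(est0$beta), 3 * est0$se)
  # the depression-scale design: 102 instruments, effect 0.84
  est <- mr_ivw(simulate_mr_instruments(102, 0.84, se_scale = 0.01,
                                        seed = 65))
  expect_equal(est$beta, 0.84, tolerance = 0.05)
})

test_that("IVW confidence intervals achieve nominal coverage (property)", {
  nrep <- 200
  covered <- 0L
  qp <- numeric(nrep)
  for (r in seq_len(nrep)) {
    d <- simulate_mr_instruments(40, 0.6, se_scale = 0.03, seed = 6000 + r)
    est <- mr_ivw(d)
    ci <- est$beta + c(-1.96, 1.96) * est$se
    if (ci[1] <= 0.6 && 0.6 <= ci[2]) covered <- covered + 1L
    qp[r] <- est$Q_p
  }
  expect_lt(abs(covered / nrep - 0.95), 3 * sqrt(0.95 * 0.05 / nrep))
  # heterogeneity p-values are uniform when the model is correctly specified
  expect_gt(ks.test(qp, "punif")$p.value, 0.001)
})

test_that("two-group MR difference test matches the z formula", {
  same <- mr_group_difference(list(beta = 1, se = 0.2),
                              list(beta = 1, se = 0.3))
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  # printed-scale inputs: adult 1.58 (0.29) vs child 0.35 (0.35)
  gd <- mr_group_difference(list(beta = 0.35, se = 0.35),
                            list(beta = 1.58, se = 0.29))
  expect_equal(gd$difference, 1.23)
  expect_equal(gd$se, sqrt(0.29^2 + 0.35^2), tolerance = 1e-12)
  expect_equal(gd$z, 1.23 / sqrt(0.29^2 + 0.35^2), tolerance = 1e-12)
  expect_equal(gd$p, 0.006808, tolerance = 1e-4)
  doubled <- mr_group_difference(list(beta = 0.35, se = 0.70),
                                 list(beta = 1.58, se = 0.58))
  expect_equal(doubled$se^2, 4 * gd$se^2, tolerance = 1e-12)
})
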