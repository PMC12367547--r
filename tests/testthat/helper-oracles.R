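# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: explicit normal equations, closed forms and
# brute-force resampling only.

# OLS slope/se/p by explicit normal equations (matrix inversion).
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  XtX_inv <- solve(t(X) %*% X)
  b <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * XtX_inv))
  tv <- b / se
  list(beta = b[2], se = se[2], p = 2 * pt(-abs(tv[2]), df))
}

# Closed-form IVW: weighted least squares through the origin, weights 1/se^2.
ivw_oracle <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  list(beta = beta, se = se)
}

# Brute-force twin-pair generator, written independently of the package.
brute_force_twins <- function(n, p, beta1, beta2, h2) {
  G <- rbinom(n, 2, p)
  s2v <- 2 * p * beta2
  z <- rnorm(n, 0, sqrt(h2 - 2 * p * (1 - p) * beta1^2))
  yA <- beta1 * G + z + rnorm(n, 0, sqrt(beta2 * G)) +
    rnorm(n, 0, sqrt(1 - h2 - s2v))
  yB <- beta1 * G + z + rnorm(n, 0, sqrt(beta2 * G)) +
    rnorm(n, 0, sqrt(1 - h2 - s2v))
  list(G = G, yA = yA, yB = yB)
}

# Empirical DRM power/size through the package's public surface.
empirical_drm_power <- function(beta2, n, p, reps, alpha, seed,
                                beta1 = 0) {
  hits <- 0L
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  for (i in seq_len(reps)) {
    prm <- sim_params(p = p, beta1 = beta1, beta2 = beta2,
                      sigma2_g = 2 * p * (1 - p) * beta1^2,
                      n_individuals = n, seed = seeds[i])
    pc <- simulate_population_cohort(prm)
    if (drm_test(pc$y, pc$G)$p < alpha) hits <- hits + 1L
  }
  hits / reps
}

# A small clean summary-statistic row for QC fixtures.
sumstat_row <- function(snp, chr = 1, pos, A1, A2, eaf, beta = 0.01,
                        se = 0.02, p = 0.6, n = 1000, info = 0.99) {
  data.frame(snp = snp, chr = chr, pos = pos, A1 = A1, A2 = A2, eaf = eaf,
             beta = beta, se = se, p = p, n = n, info = info,
             stringsAsFactors = FALSE)
}
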