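#' Analytic power approximation for the DRM test
#'
#' Normal approximation for the deviation-regression slope under the twin
#' generative model. Conditional on genotype `g`, the phenotype variance is
#' `c + beta2 * g` with `c = 1 - 2p(1-p)beta1^2 - sigma2_v`; the expected
#' DRM slope is `sqrt(2/pi) * beta2 / (2 * sqrt(c + 2p*beta2))` (folded-normal
#' mean, linearized at the mean genotype) and its standard error is
#' `sqrt((1 - 2/pi) * (c + 2p*beta2) / (n * 2p(1-p)))`.
#'
#' @param params A [sim_params()] object (only `p`, `beta1`, `beta2` are
#'   used; the power does not depend on `sigma2_g`).
#' @param n Number of unrelated individuals.
#' @param alpha Two-sided significance level.
#' @return Approximate two-sided power,
#'   `Phi(|slope|/SE - z_{1-alpha/2}) + Phi(-|slope|/SE - z_{1-alpha/2})`;
#'   equals `alpha` at `beta2 = 0`.
#' @export
analytic_drm_power <- function(params, n, alpha = 5e-8) {
  stopifnot(inherits(params, "sim_params"))
  p <- params$p; beta1 <- params$beta1; beta2 <- params$beta2
  if (beta2 < 0) stop("`beta2` must be non-negative")
  c0 <- 1 - 2 * p * (1 - p) * beta1^2 - params$sigma2_v
  slope <- sqrt(2 / pi) * beta2 / (2 * sqrt(c0 + 2 * p * beta2))
  se <- sqrt((1 - 2 / pi) * (c0 + 2 * p * beta2) / (n * 2 * p * (1 - p)))
  z_crit <- stats::qnorm(1 - alpha / 2)
  lambda <- abs(slope) / se
  stats::pnorm(lambda - z_crit) + stats::pnorm(-lambda - z_crit)
}

#' Calibrate the variance effect to a target DRM power
#'
#' Bisection on [analytic_drm_power()]: returns the `beta2` at which the DRM
#' test attains `target_power` in a population sample of size `n`. The
#' paper-scale calibration is 80% power at n = 500,000, p = 0.3, beta1 = 0,
#' alpha = 5e-8.
#'
#' @param target_power Target power in (0, 1).
#' @param n Population sample size.
#' @param p Allele frequency.
#' @param beta1 Additive effect.
#' @param alpha Significance level.
#' @param tol Convergence tolerance on power.
#' @return The calibrated `beta2`.
#' @examples
#' calibrate_beta2(0.8, n = 5e5, p = 0.3, beta1 = 0, alpha = 5e-8)
#' @export
calibrate_beta2 <- function(target_power, n, p = 0.3, beta1 = 0,
                            alpha = 5e-8, tol = 1e-4) {
  if (target_power <= 0 || target_power >= 1)
    stop("`target_power` must lie in (0, 1)")
  pow <- function(b2) {
    prm <- sim_params(p = p, beta1 = beta1, beta2 = b2,
                      sigma2_g = 2 * p * (1 - p) * beta1^2)
    analytic_drm_power(prm, n, alpha)
  }
  lo <- 0; hi <- 1e-4
  while (pow(hi) < target_power) {
    hi <- hi * 2
    if (2 * p * hi > 1)
      stop("target power unreachable within the beta2 search bracket")
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (abs(pow(mid) - target_power) < tol) return(mid)
    if (pow(mid) < target_power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# One replicate of the MZ power experiment: raw |yA - yB| regressed on G.
.mz_power_rep <- function(params) {
  ch <- simulate_twin_cohort(params)
  mz_diff_test(abs(ch$yA - ch$yB), ch$G)$p
}

# Empirical DRM power/size at one parameter set.
.drm_power_empirical <- function(params, n, alpha, reps, seeds) {
  hits <- 0L
  prm <- params
  prm$n_individuals <- as.integer(n)
  for (i in seq_len(reps)) {
    prm$seed <- seeds[[i]]
    pc <- simulate_population_cohort(prm)
    if (drm_test(pc$y, pc$G)$p < alpha) hits <- hits + 1L
  }
  hits / reps
}

#' Power comparison: MZ differences versus population DRM
#'
#' For each narrow-sense heritability on `h2_grid`, simulates `reps` twin
#' cohorts of `n_pairs` pairs and records the fraction in which the
#' MZ-differences regression (absolute difference on genotype, no
#' covariates) is significant at `alpha`. DRM power is computed once for a
#' matched cohort of `2 * n_pairs` unrelated individuals and once for a
#' large cohort of `n_large` (it does not depend on the heritability under
#' this model).
#'
#' @param h2_grid Numeric vector of heritabilities (`sigma2_g` values).
#' @param beta2 Variance effect, typically from [calibrate_beta2()].
#' @param n_pairs Number of MZ pairs per replicate.
#' @param n_large Large-cohort population size.
#' @param p Allele frequency.
#' @param beta1 Additive effect.
#' @param alpha Significance level (genome-wide 5e-8 by default).
#' @param reps Replicates per grid point.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A `power_result` list with `h2_grid`, `power_mz`,
#'   `power_drm_matched`, `power_drm_large`, `mc_se` (binomial SEs for
#'   `power_mz`), and the settings used.
#' @export
power_curve <- function(h2_grid, beta2, n_pairs = 10000, n_large = 500000,
                        p = 0.3, beta1 = 0, alpha = 5e-8, reps = 500,
                        seed = NULL) {
  seeds <- .derive_seeds(seed, length(h2_grid) * reps + 2 * reps)
  power_mz <- rep(NA_real_, length(h2_grid))
  k <- 0L
  for (j in seq_along(h2_grid)) {
    h2 <- h2_grid[j]
    sigma2_v <- 2 * p * beta2
    if (h2 + sigma2_v > 1 || h2 < 2 * p * (1 - p) * beta1^2) {
      warning("skipping infeasible grid point h2 = ", h2)
      k <- k + reps
      next
    }
    hits <- 0L
    for (i in seq_len(reps)) {
      k <- k + 1L
      prm <- sim_params(p = p, beta1 = beta1, beta2 = beta2, sigma2_g = h2,
                        n_pairs = n_pairs, seed = seeds[[k]])
      if (.mz_power_rep(prm) < alpha) hits <- hits + 1L
    }
    power_mz[j] <- hits / reps
  }
  base_prm <- sim_params(p = p, beta1 = beta1, beta2 = beta2,
                         sigma2_g = 2 * p * (1 - p) * beta1^2)
  drm_matched <- .drm_power_empirical(base_prm, 2 * n_pairs, alpha, reps,
                                      seeds[(k + 1):(k + reps)])
  drm_large <- .drm_power_empirical(base_prm, n_large, alpha, reps,
                                    seeds[(k + reps + 1):(k + 2 * reps)])
  structure(list(h2_grid = h2_grid, power_mz = power_mz,
                 power_drm_matched = drm_matched,
                 power_drm_large = drm_large,
                 mc_se = sqrt(pmax(power_mz * (1 - power_mz), 1e-12) / reps),
                 n_pairs = n_pairs, n_large = n_large, reps = reps,
                 alpha_sig = alpha, beta2_used = beta2, p = p, beta1 = beta1),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("vQTL power study (beta2 = %.4g, %d reps, alpha = %g)\n",
              x$beta2_used, x$reps, x$alpha_sig))
  cat(sprintf("  DRM power: %.3f (n = %d matched), %.3f (n = %d)\n",
              x$power_drm_matched, 2 * x$n_pairs, x$power_drm_large,
              x$n_large))
  print(data.frame(h2 = x$h2_grid, power_mz = x$power_mz))
  invisible(x)
}

#' False-positive study under LD tagging of an additive locus
#'
#' A causal locus carries an additive effect (`beta1`) but no variance
#' effect (`beta2 = 0`); the vQTL tests are run at a second, tagging locus
#' in LD `r2` with the causal one ("phantom vQTL" design). For each `r2` on
#' the grid the fraction of replicates significant at `alpha` is recorded
#' for the MZ-differences test (twin cohorts of `n_pairs`) and the DRM test
#' (`n_individuals` unrelated individuals).
#'
#' @param r2_grid LD grid in \[0, 1\]; default `seq(0, 1, 0.1)`.
#' @param reps Replicates per grid point (500 by default).
#' @param p Allele frequency (0.1).
#' @param beta1 Additive effect at the causal locus (0.1).
#' @param h2 Narrow-sense heritability (0.5).
#' @param n_pairs MZ pairs per replicate.
#' @param n_individuals Unrelated individuals per replicate.
#' @param alpha Significance level used for false-positive counting (0.05).
#' @param seed Master seed.
#' @return An `fdr_result` list with `r2_grid`, `fpr_mz`, `fpr_drm`, `mc_se`,
#'   and the settings used.
#' @export
fdr_study <- function(r2_grid = seq(0, 1, 0.1), reps = 500, p = 0.1,
                      beta1 = 0.1, h2 = 0.5, n_pairs = 10000,
                      n_individuals = 500000, alpha = 0.05, seed = NULL) {
  if (any(r2_grid < 0 | r2_grid > 1)) stop("`r2_grid` must lie in [0, 1]")
  seeds <- .derive_seeds(seed, length(r2_grid) * reps)
  fpr_mz <- fpr_drm <- rep(NA_real_, length(r2_grid))
  k <- 0L
  sigma2_z <- h2 - 2 * p * (1 - p) * beta1^2
  for (j in seq_along(r2_grid)) {
    hit_mz <- hit_drm <- 0L
    for (i in seq_len(reps)) {
      k <- k + 1L
      prm <- sim_params(p = p, beta1 = beta1, beta2 = 0, sigma2_g = h2,
                        n_pairs = n_pairs,
                        n_individuals = n_individuals, seed = NULL)
      res <- .with_seed(seeds[[k]], {
        # twin cohort at the causal locus plus its tagging locus
        loci_t <- simulate_tagged_locus(prm, r2_grid[j], n = n_pairs)
        zt <- stats::rnorm(n_pairs, 0, sqrt(sigma2_z))
        mu <- beta1 * loci_t$G_causal + zt
        yA <- mu + stats::rnorm(n_pairs, 0, sqrt(1 - h2))
        yB <- mu + stats::rnorm(n_pairs, 0, sqrt(1 - h2))
        # population cohort at an independently drawn locus pair
        loci_p <- simulate_tagged_locus(prm, r2_grid[j], n = n_individuals)
        y <- beta1 * loci_p$G_causal +
          stats::rnorm(n_individuals, 0, sqrt(sigma2_z)) +
          stats::rnorm(n_individuals, 0, sqrt(1 - h2))
        c(mz = mz_diff_test(abs(yA - yB), loci_t$G_tag)$p,
          drm = drm_test(y, loci_p$G_tag)$p)
      })
      if (res["mz"] < alpha) hit_mz <- hit_mz + 1L
      if (res["drm"] < alpha) hit_drm <- hit_drm + 1L
    }
    fpr_mz[j] <- hit_mz / reps
    fpr_drm[j] <- hit_drm / reps
  }
  structure(list(r2_grid = r2_grid, fpr_mz = fpr_mz, fpr_drm = fpr_drm,
                 mc_se = sqrt(alpha * (1 - alpha) / reps),
                 reps = reps, p = p, beta1 = beta1, h2 = h2,
                 n_pairs = n_pairs, n_individuals = n_individuals,
                 alpha_sig = alpha),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("Phantom-vQTL false-positive study (beta1 = %g, h2 = %g, p = %g, %d reps)\n",
              x$beta1, x$h2, x$p, x$reps))
  print(data.frame(r2 = x$r2_grid, fpr_mz = x$fpr_mz, fpr_drm = x$fpr_drm))
  invisible(x)
}
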