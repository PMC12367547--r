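#' Simulate a cohort of monozygotic twin pairs
#'
#' Draws `params$n_pairs` MZ pairs from the twin generative model (see
#' [sim_params()]). Genotype and polygenic value are shared within a pair;
#' the vQTL term `v` and the residual `e` are drawn independently for each
#' twin, so all within-pair variability comes from `v + e`.
#'
#' @param params A [sim_params()] object.
#' @param covariates Logical; attach a simulated covariate table
#'   (age, sex, PC1--PC10, see [simulate_covariates()])?
#' @return A `twin_cohort` object: list with `pair_id`, `G` (shared genotype,
#'   0/1/2), `z` (shared polygenic value), `yA`, `yB` (per-twin phenotypes),
#'   `covariates` (data frame or `NULL`) and `params`.
#' @examples
#' ch <- simulate_twin_cohort(sim_params(p = 0.3, sigma2_g = 0.5, seed = 1))
#' var(ch$yA - ch$yB)  # ~ 2 * sigma2_e when beta2 = 0
#' @export
simulate_twin_cohort <- function(params, covariates = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    n <- params$n_pairs
    G <- stats::rbinom(n, 2L, params$p)
    sigma2_z <- params$sigma2_g - 2 * params$p * (1 - params$p) * params$beta1^2
    z <- stats::rnorm(n, 0, sqrt(sigma2_z))
    mu <- params$alpha_intercept + params$beta1 * G + z
    sd_v <- sqrt(params$beta2 * G)
    sd_e <- sqrt(params$sigma2_e)
    yA <- mu + stats::rnorm(n, 0, sd_v) + stats::rnorm(n, 0, sd_e)
    yB <- mu + stats::rnorm(n, 0, sd_v) + stats::rnorm(n, 0, sd_e)
    cov_tab <- if (covariates) simulate_covariates(n) else NULL
    structure(list(pair_id = paste0("pair", seq_len(n)), G = G, z = z,
                   yA = yA, yB = yB, covariates = cov_tab, params = params),
              class = "twin_cohort")
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("MZ twin cohort: %d pairs (p = %g, beta1 = %g, beta2 = %g, h2 = %g)\n",
              length(x$G), x$params$p, x$params$beta1, x$params$beta2,
              x$params$sigma2_g))
  invisible(x)
}

#' @export
as.data.frame.twin_cohort <- function(x, ...) {
  out <- data.frame(pair_id = x$pair_id, G = x$G, yA = x$yA, yB = x$yB,
                    stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  out
}

#' Simulate a cohort of unrelated individuals
#'
#' Marginally equivalent to drawing a twin cohort and keeping one randomly
#' chosen twin per pair; sampled directly for efficiency.
#'
#' @param params A [sim_params()] object; `params$n_individuals` individuals
#'   are drawn.
#' @return A `population_cohort` object: list with `id`, `G`, `y`, `params`.
#' @export
simulate_population_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    n <- params$n_individuals
    G <- stats::rbinom(n, 2L, params$p)
    sigma2_z <- params$sigma2_g - 2 * params$p * (1 - params$p) * params$beta1^2
    y <- params$alpha_intercept + params$beta1 * G +
      stats::rnorm(n, 0, sqrt(sigma2_z)) +
      stats::rnorm(n, 0, sqrt(params$beta2 * G)) +
      stats::rnorm(n, 0, sqrt(params$sigma2_e))
    structure(list(id = paste0("ind", seq_len(n)), G = G, y = y,
                   params = params), class = "population_cohort")
  })
}

#' @export
print.population_cohort <- function(x, ...) {
  cat(sprintf("Population cohort: %d unrelated individuals (p = %g)\n",
              length(x$G), x$params$p))
  invisible(x)
}

#' Simulate a pair of loci in linkage disequilibrium
#'
#' Constructs genotypes at a causal locus and a tagging locus with equal
#' allele frequencies `p` and haplotype disequilibrium
#' \eqn{D = \sqrt{r^2} p (1-p)}, so the haplotype correlation is
#' \eqn{r = \sqrt{r^2}} and the genotype-level squared correlation equals
#' `r2` in expectation. Genotypes are sums of two independent haplotypes.
#'
#' @param params A [sim_params()] object; `n_pairs` genotype pairs are drawn
#'   (use the result with twin cohorts via `G_causal`).
#' @param r2 Target squared LD correlation in \[0, 1\].
#' @param n Number of genotype pairs; defaults to `params$n_pairs`.
#' @return A `tagged_locus_pair` object: list with `G_causal`, `G_tag`,
#'   `r2_target`.
#' @export
simulate_tagged_locus <- function(params, r2, n = params$n_pairs) {
  stopifnot(inherits(params, "sim_params"))
  if (r2 < 0 || r2 > 1) stop("`r2` must lie in [0, 1]")
  p <- params$p
  r <- sqrt(r2)
  D <- r * p * (1 - p)
  # conditional allele probabilities at the tag given the causal haplotype
  q1 <- p + D / p          # P(tag = 1 | causal = 1)
  q0 <- p - D / (1 - p)    # P(tag = 1 | causal = 0)
  if (q1 > 1 + 1e-12 || q0 < -1e-12)
    stop("requested D = ", signif(D, 4),
         " exceeds the feasible bound for p = ", p)
  q1 <- min(q1, 1); q0 <- max(q0, 0)
  .with_seed(params$seed, {
    hap_a1 <- stats::rbinom(n, 1L, p)
    hap_a2 <- stats::rbinom(n, 1L, p)
    hap_b1 <- stats::rbinom(n, 1L, q0 + (q1 - q0) * hap_a1)
    hap_b2 <- stats::rbinom(n, 1L, q0 + (q1 - q0) * hap_a2)
    structure(list(G_causal = hap_a1 + hap_a2, G_tag = hap_b1 + hap_b2,
                   r2_target = r2), class = "tagged_locus_pair")
  })
}

#' Exact genotype-level LD correlation implied by the haplotype construction
#'
#' Enumerates the four haplotype frequencies implied by allele frequency `p`
#' and disequilibrium \eqn{D = \sqrt{r^2} p(1-p)} and returns the exact
#' squared correlation of the two genotype counts. Useful as an enumeration
#' oracle for [simulate_tagged_locus()].
#'
#' @param p Allele frequency at both loci.
#' @param r2 Target squared LD.
#' @return The exact squared genotype correlation (equal to `r2`).
#' @export
tagged_locus_r2_exact <- function(p, r2) {
  D <- sqrt(r2) * p * (1 - p)
  # haplotype frequencies: (1,1), (1,0), (0,1), (0,0)
  f <- c(p * p + D, p * (1 - p) - D, (1 - p) * p - D, (1 - p)^2 + D)
  if (any(f < -1e-12)) stop("infeasible haplotype frequencies")
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  Ea <- sum(f * a); Eb <- sum(f * b)
  cov_hap <- sum(f * a * b) - Ea * Eb
  va <- Ea * (1 - Ea); vb <- Eb * (1 - Eb)
  # genotypes are sums of two iid haplotypes: correlations coincide
  (2 * cov_hap)^2 / (2 * va * 2 * vb)
}

#' Simulate a covariate table for twin pairs
#'
#' Test-fixture covariates: age uniform over `age_range`, sex Bernoulli(0.5)
#' coded 0/1, and ten independent standard-normal genetic principal
#' components (PC1--PC10).
#'
#' @param n_pairs Number of rows.
#' @param seed Optional integer seed.
#' @param age_range Length-2 numeric, uniform age range in years.
#' @return A data frame with columns `age`, `sex`, `PC1` ... `PC10`.
#' @export
simulate_covariates <- function(n_pairs, seed = NULL, age_range = c(8, 60)) {
  stopifnot(n_pairs > 0, length(age_range) == 2)
  .with_seed(seed, {
    pcs <- matrix(stats::rnorm(n_pairs * 10L), ncol = 10L,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    data.frame(age = stats::runif(n_pairs, age_range[1], age_range[2]),
               sex = stats::rbinom(n_pairs, 1L, 0.5),
               pcs)
  })
}

#' Simulate a harmonized two-sample MR instrument table
#'
#' Parameter-recovery harness for the Mendelian-randomization module:
#' exposure effects are drawn from a normal distribution with known standard
#' errors, and outcome effects follow
#' `beta_out = true_effect * beta_exp + N(0, se_out^2)`.
#'
#' @param n_snps Number of instruments (at least 2).
#' @param true_effect True causal effect of the exposure on the outcome.
#' @param se_scale Outcome standard error for every instrument.
#' @param seed Optional integer seed.
#' @param exp_mean,exp_sd Mean and SD of the exposure effect distribution.
#' @param se_exp Exposure standard error (reported, not used in IVW weights).
#' @return A data frame of class `mr_input` with columns `snp`, `A1`, `A2`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @export
simulate_mr_instruments <- function(n_snps, true_effect, se_scale = 0.02,
                                    seed = NULL, exp_mean = 0.04,
                                    exp_sd = 0.01, se_exp = 0.005) {
  if (n_snps < 2) stop("`n_snps` must be at least 2")
  .with_seed(seed, {
    beta_exp <- stats::rnorm(n_snps, exp_mean, exp_sd)
    beta_out <- true_effect * beta_exp + stats::rnorm(n_snps, 0, se_scale)
    out <- data.frame(snp = paste0("rs", seq_len(n_snps)),
                      A1 = "A", A2 = "G",
                      beta_exp = beta_exp, se_exp = se_exp,
                      beta_out = beta_out, se_out = se_scale,
                      stringsAsFactors = FALSE)
    class(out) <- c("mr_input", "data.frame")
    out
  })
}
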