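#' Simulation parameters for the twin generative model
#'
#' Bundles and validates the parameters of the data-generating model used
#' throughout the package. A phenotype for twin t of MZ pair i is
#' \deqn{y_{i,t} = \alpha + \beta_1 G_i + z_i + v_{i,t} + e_{i,t}}
#' where \eqn{G_i ~ Binom(2, p)} is shared by both twins,
#' \eqn{z_i ~ N(0, \sigma^2_g - 2p(1-p)\beta_1^2)} is the shared residual
#' polygenic value, \eqn{v_{i,t} ~ N(0, \beta_2 G_i)} is the per-allele
#' variance-inflation (vQTL) term drawn independently per twin, and
#' \eqn{e_{i,t} ~ N(0, 1 - \sigma^2_g - \sigma^2_v)} is the independent
#' residual. With \eqn{\sigma^2_v = E[var(v | G)] = 2 p \beta_2}, the total
#' phenotypic variance is 1 by construction.
#'
#' @param p Effect-allele frequency, strictly in (0, 1).
#' @param beta1 Additive SNP effect, phenotype SD units per allele.
#' @param beta2 Per-allele variance-inflation effect (variance units per
#'   allele); must be non-negative.
#' @param sigma2_g Genetic variance \eqn{\sigma^2_g} (narrow-sense
#'   heritability on the unit-variance scale). Must satisfy
#'   \eqn{\sigma^2_g \ge 2p(1-p)\beta_1^2} and
#'   \eqn{\sigma^2_g + \sigma^2_v \le 1}.
#' @param alpha_intercept Intercept, default 0.
#' @param n_pairs Number of MZ pairs to simulate.
#' @param n_individuals Number of unrelated individuals to simulate.
#' @param seed Integer random seed, or `NULL` to use the current RNG stream.
#' @param alpha_sig Significance threshold used when counting discoveries in
#'   the power / false-discovery studies.
#'
#' @return An object of class `sim_params`: a validated list with the above
#'   fields plus the derived `sigma2_v = 2 * p * beta2` and the residual
#'   variance `sigma2_e = 1 - sigma2_g - sigma2_v`.
#' @examples
#' sim_params(p = 0.3, beta1 = 0, beta2 = 0.02, sigma2_g = 0.5)
#' @export
sim_params <- function(p, beta1 = 0, beta2 = 0, sigma2_g = 0,
                       alpha_intercept = 0, n_pairs = 10000L,
                       n_individuals = 20000L, seed = NULL,
                       alpha_sig = 5e-8) {
  stopifnot(is.numeric(p), is.numeric(beta1), is.numeric(beta2),
            is.numeric(sigma2_g))
  if (p <= 0 || p >= 1)
    stop("allele frequency `p` must lie strictly in (0, 1)")
  if (beta2 < 0)
    stop("variance effect `beta2` must be non-negative")
  if (sigma2_g < 2 * p * (1 - p) * beta1^2)
    stop("`sigma2_g` must be at least 2*p*(1-p)*beta1^2 ",
         "(the polygenic variance sigma2_g - 2p(1-p)beta1^2 is negative)")
  sigma2_v <- 2 * p * beta2
  if (sigma2_g + sigma2_v > 1 + 1e-12)
    stop("`sigma2_g` + sigma2_v exceeds 1 ",
         "(the residual variance 1 - sigma2_g - sigma2_v is negative)")
  if (n_pairs < 1 || n_individuals < 1)
    stop("sample sizes must be positive")
  structure(list(
    p = p, beta1 = beta1, beta2 = beta2, sigma2_g = sigma2_g,
    alpha_intercept = alpha_intercept,
    n_pairs = as.integer(n_pairs), n_individuals = as.integer(n_individuals),
    seed = seed, alpha_sig = alpha_sig,
    sigma2_v = sigma2_v, sigma2_e = 1 - sigma2_g - sigma2_v
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Twin generative-model parameters\n")
  cat(sprintf("  p = %g, beta1 = %g, beta2 = %g\n", x$p, x$beta1, x$beta2))
  cat(sprintf("  sigma2_g = %g, sigma2_v = %g, sigma2_e = %g\n",
              x$sigma2_g, x$sigma2_v, x$sigma2_e))
  cat(sprintf("  n_pairs = %d, n_individuals = %d, alpha_sig = %g\n",
              x$n_pairs, x$n_individuals, x$alpha_sig))
  invisible(x)
}
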