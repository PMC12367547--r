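#' Harmonize exposure and outcome summary statistics for two-sample MR
#'
#' Joins exposure and outcome tables on `chr:pos`, aligns the outcome effect
#' to the exposure's effect allele (sign flip when allele labels are
#' swapped, strand flips tolerated), drops variants whose allele sets
#' differ, and drops palindromic variants whose orientation cannot be
#' resolved by allele frequency.
#'
#' @param exposure,outcome Data frames with `snp`, `chr`, `pos`, `A1`, `A2`,
#'   `beta`, `se` (and optionally `eaf` for palindromic resolution).
#' @param palindromic_margin Minimum |eaf - 0.5| for frequency resolution of
#'   palindromic variants; used only when both tables carry `eaf`.
#' @return An `mr_input` data frame: `snp`, `A1`, `A2`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @export
mr_harmonize <- function(exposure, outcome, palindromic_margin = 0.08) {
  for (nm in c("chr", "pos", "A1", "A2", "beta", "se"))
    if (!nm %in% names(exposure) || !nm %in% names(outcome))
      stop("both tables must carry column `", nm, "`")
  key_e <- paste(exposure$chr, exposure$pos, sep = ":")
  key_o <- paste(outcome$chr, outcome$pos, sep = ":")
  idx <- match(key_e, key_o)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no shared variants between exposure and outcome")
  e <- exposure[keep, ]; o <- outcome[idx[keep], ]
  eA1 <- toupper(e$A1); eA2 <- toupper(e$A2)
  oA1 <- toupper(o$A1); oA2 <- toupper(o$A2)

  direct <- oA1 == eA1 & oA2 == eA2
  swapped <- oA1 == eA2 & oA2 == eA1
  flipped <- .complement_allele(oA1) == eA1 & .complement_allele(oA2) == eA2
  flip_swap <- .complement_allele(oA1) == eA2 & .complement_allele(oA2) == eA1
  pal <- .is_palindromic(eA1, eA2)

  action <- rep(NA_character_, nrow(e))
  action[(direct | flipped) & !pal] <- "keep"
  action[(swapped | flip_swap) & !pal] <- "swap"
  if ("eaf" %in% names(e) && "eaf" %in% names(o)) {
    pm <- pal & (direct | swapped | flipped | flip_swap)
    inf <- pm & abs(e$eaf - 0.5) > palindromic_margin &
      abs(o$eaf - 0.5) > palindromic_margin
    action[inf & sign(e$eaf - 0.5) == sign(o$eaf - 0.5)] <- "keep"
    action[inf & sign(e$eaf - 0.5) != sign(o$eaf - 0.5)] <- "swap"
  }
  beta_out <- ifelse(action == "swap", -o$beta, o$beta)
  ok <- !is.na(action)
  out <- data.frame(snp = e$snp[ok], A1 = eA1[ok], A2 = eA2[ok],
                    beta_exp = e$beta[ok], se_exp = e$se[ok],
                    beta_out = beta_out[ok], se_out = o$se[ok],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$snp), ]
  class(out) <- c("mr_input", "data.frame")
  out
}

#' Inverse-variance-weighted Mendelian randomization estimate
#'
#' Fixed-effect IVW estimator: weighted least squares of the outcome effects
#' on the exposure effects through the origin with weights `1/se_out^2`,
#' \deqn{\hat\beta = \frac{\sum \beta_{X,j} \beta_{Y,j} / se_{Y,j}^2}
#'                        {\sum \beta_{X,j}^2 / se_{Y,j}^2}, \quad
#'       se = \sqrt{1 / \sum \beta_{X,j}^2 / se_{Y,j}^2},}
#' with two-sided normal p and Cochran's Q heterogeneity statistic
#' \eqn{Q = \sum (\beta_{Y,j} - \hat\beta \beta_{X,j})^2 / se_{Y,j}^2} on
#' `n_snps - 1` degrees of freedom. With a single instrument the Wald ratio
#' `beta_out/beta_exp` with `se = se_out/|beta_exp|` is returned.
#' `method = "random"` inflates the SE by the multiplicative
#' over-dispersion factor `max(1, sqrt(Q / Q_df))`.
#'
#' @param data An `mr_input` table ([mr_harmonize()] or
#'   [simulate_mr_instruments()]).
#' @param method `"fixed"` (default) or `"random"` (multiplicative
#'   random-effects SE).
#' @return An `mr_result` list: `beta`, `se`, `p`, `n_snps`, `Q`, `Q_df`,
#'   `Q_p`, `method`.
#' @export
mr_ivw <- function(data, method = c("fixed", "random")) {
  method <- match.arg(method)
  if (any(data$se_out <= 0)) stop("`se_out` must be positive")
  drop0 <- data$beta_exp == 0
  if (any(drop0)) {
    warning(sum(drop0), " instrument(s) with zero exposure effect dropped")
    data <- data[!drop0, ]
  }
  n <- nrow(data)
  if (n < 1) stop("no usable instruments")
  if (n == 1) {
    beta <- data$beta_out / data$beta_exp
    se <- data$se_out / abs(data$beta_exp)
    return(structure(list(beta = beta, se = se,
                          p = 2 * stats::pnorm(-abs(beta / se)),
                          n_snps = 1L, Q = 0, Q_df = 0L, Q_p = NA_real_,
                          method = method), class = "mr_result"))
  }
  w <- 1 / data$se_out^2
  sxx <- sum(w * data$beta_exp^2)
  beta <- sum(w * data$beta_exp * data$beta_out) / sxx
  se <- sqrt(1 / sxx)
  Q <- sum(w * (data$beta_out - beta * data$beta_exp)^2)
  Q_df <- n - 1L
  if (method == "random") se <- se * max(1, sqrt(Q / Q_df))
  structure(list(beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_snps = as.integer(n), Q = Q, Q_df = Q_df,
                 Q_p = stats::pchisq(Q, Q_df, lower.tail = FALSE),
                 method = method), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW MR estimate: beta = %.3f (se %.3f), p = %.3g, %d instruments\n",
              x$beta, x$se, x$p, x$n_snps))
  if (x$Q_df > 0)
    cat(sprintf("  heterogeneity: Q = %.2f on %d df (p = %.3g)\n",
                x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

#' Difference between two independent MR estimates
#'
#' Two-group comparison of IVW slopes (e.g. adults versus children),
#' treating the samples as independent:
#' `difference = beta_b - beta_a`, `se = sqrt(se_a^2 + se_b^2)`, two-sided
#' normal p. Numerically equivalent to a group-by-exposure interaction term
#' for a two-group comparison.
#'
#' @param res_a,res_b `mr_result` objects (or lists with `beta` and `se`).
#' @return List with `difference`, `se`, `z`, `p`.
#' @examples
#' mr_group_difference(list(beta = 0.35, se = 0.35),
#'                     list(beta = 1.58, se = 0.29))
#' @export
mr_group_difference <- function(res_a, res_b) {
  diff <- res_b$beta - res_a$beta
  se <- sqrt(res_a$se^2 + res_b$se^2)
  z <- diff / se
  list(difference = diff, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
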