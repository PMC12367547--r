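#' Absolute within-pair phenotype difference
#'
#' The MZ-differences score starts from `|yA - yB|` for each pair. Pairs with
#' a missing phenotype for either twin are excluded (complete-pair
#' requirement) and reported via the `excluded` attribute.
#'
#' @param cohort A `twin_cohort`, or a list/data frame with `yA` and `yB`.
#' @return Numeric vector of absolute differences, named by `pair_id` when
#'   available, with attribute `excluded` (integer indices of dropped pairs).
#' @examples
#' absolute_pair_difference(list(yA = c(1, 2), yB = c(3, 2)))
#' @export
absolute_pair_difference <- function(cohort) {
  yA <- cohort$yA; yB <- cohort$yB
  if (is.null(yA) || is.null(yB)) stop("cohort must carry `yA` and `yB`")
  if (length(yA) != length(yB)) stop("`yA` and `yB` differ in length")
  keep <- is.finite(yA) & is.finite(yB)
  if (!all(keep))
    message(sum(!keep), " pair(s) excluded for incomplete phenotypes")
  d <- abs(yA[keep] - yB[keep])
  if (!is.null(cohort$pair_id)) names(d) <- cohort$pair_id[keep]
  attr(d, "excluded") <- which(!keep)
  d
}

#' Residualize a vector on a covariate table
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus all
#' columns of `covariates`. Residuals are orthogonal to every covariate
#' column. Rows with missing covariates are excluded (and reported); a
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param values Numeric vector.
#' @param covariates Data frame (or matrix) of covariates, same row count.
#' @return Numeric vector of residuals for the retained rows, with attribute
#'   `excluded` (indices of dropped rows).
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) > 0 && nrow(covariates) != length(values))
    stop("`covariates` must have one row per value")
  keep <- is.finite(values)
  if (ncol(covariates) > 0) keep <- keep & stats::complete.cases(covariates)
  if (ncol(covariates) == 0)
    covariates <- data.frame(row.names = seq_along(values))
  if (!all(keep))
    message(sum(!keep), " row(s) excluded for missing covariates/values")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates[keep, , drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qr_x, values[keep])
  attr(res, "excluded") <- which(!keep)
  res
}

#' Rank-based inverse-normal transform
#'
#' Z-standardizes, then maps each value to
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} where `r` is its rank (ties get
#' the average rank) and `c` is the rank offset, Blom's 3/8 by default. The
#' result is monotone in the input and follows the normal-scores
#' distribution given the ranks.
#'
#' @param values Numeric vector, length at least 2, not all identical.
#' @param offset Rank offset `c`; default `3/8` (Blom).
#' @return Numeric vector of normal scores.
#' @examples
#' inverse_normal_transform(c(10, 20, 30))
#' @export
inverse_normal_transform <- function(values, offset = 3/8) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (max(values) - min(values) == 0)
    stop("all values identical: no ordering information")
  z <- (values - mean(values)) / stats::sd(values)
  r <- rank(z, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Prepare the MZ-differences phenotype
#'
#' Full preparation pipeline: absolute pair difference, covariate
#' residualization, standardization and rank-based inverse-normal transform.
#' Three variants are supported:
#' \describe{
#'   \item{model 1}{residualize on age, sex and the ten PCs (the primary
#'     model).}
#'   \item{model 2}{as model 1, and additionally return the within-pair
#'     phenotype mean `(yA + yB) / 2` for use as a regression covariate in
#'     [mz_diff_test()].}
#'   \item{model 3}{residualize on age and sex only (no principal
#'     components).}
#' }
#'
#' @param cohort A `twin_cohort` with a covariate table (models 1 and 2), or
#'   any list with `yA`, `yB`, `pair_id`, `covariates`.
#' @param model Integer 1, 2 or 3.
#' @param extra_covariates Optional data frame of study-specific covariates
#'   appended to the residualization design.
#' @param offset Rank offset passed to [inverse_normal_transform()].
#' @return Data frame with `pair_id`, `raw_diff`, `prepared`, `model_tag`,
#'   and `pair_mean` when `model = 2`.
#' @export
prepare_phenotype <- function(cohort, model = 1, extra_covariates = NULL,
                              offset = 3/8) {
  if (!model %in% 1:3) stop("`model` must be 1, 2 or 3")
  raw <- absolute_pair_difference(cohort)
  keep <- setdiff(seq_along(cohort$yA), attr(raw, "excluded"))
  cov_tab <- cohort$covariates
  if (is.null(cov_tab)) stop("cohort carries no covariate table")
  cov_tab <- cov_tab[keep, , drop = FALSE]
  if (!is.null(extra_covariates))
    cov_tab <- cbind(cov_tab, extra_covariates[keep, , drop = FALSE])
  pc_cols <- grep("^PC[0-9]+$", names(cov_tab), value = TRUE)
  use <- if (model == 3) setdiff(names(cov_tab), pc_cols) else names(cov_tab)
  res <- residualize(as.numeric(raw), cov_tab[, use, drop = FALSE])
  if (length(attr(res, "excluded")) > 0) {
    drop_idx <- attr(res, "excluded")
    keep <- keep[-drop_idx]
    raw <- raw[-drop_idx]
  }
  prepared <- inverse_normal_transform(res, offset = offset)
  out <- data.frame(pair_id = if (is.null(names(raw))) as.character(keep)
                    else names(raw),
                    raw_diff = as.numeric(raw),
                    prepared = prepared,
                    model_tag = model,
                    stringsAsFactors = FALSE)
  if (model == 2)
    out$pair_mean <- (cohort$yA[keep] + cohort$yB[keep]) / 2
  out
}
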