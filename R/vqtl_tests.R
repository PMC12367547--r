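#' MZ-differences vQTL association test
#'
#' Regresses the prepared MZ-differences score on genotype:
#' `prepared ~ intercept + G` (model 1 and 3), adding the within-pair
#' phenotype mean as a covariate for model 2. The slope on `G` estimates the
#' per-allele variance effect. Inference uses the t reference with n - k
#' degrees of freedom.
#'
#' @param prepared Numeric vector: the prepared differences score (or a raw
#'   absolute difference in simulation studies).
#' @param G Genotype vector: hard calls in \{0,1,2\} or dosages in \[0,2\].
#' @param model Integer 1, 2 or 3 (2 requires `pair_mean`).
#' @param pair_mean Within-pair phenotype means, required when `model = 2`.
#' @param snp_id Optional identifier carried into the result.
#' @return A list of class `assoc_result` with `snp_id`, `beta`, `se`,
#'   `statistic`, `p`, `n`, `df`, `untestable`. Monomorphic genotypes give
#'   `untestable = TRUE` with NA estimates.
#' @export
mz_diff_test <- function(prepared, G, model = 1, pair_mean = NULL,
                         snp_id = NA_character_) {
  if (length(prepared) != length(G)) stop("lengths of inputs differ")
  if (!model %in% 1:3) stop("`model` must be 1, 2 or 3")
  if (model == 2 && is.null(pair_mean))
    stop("`pair_mean` is required for model 2")
  ok <- is.finite(prepared) & is.finite(G)
  if (model == 2) ok <- ok & is.finite(pair_mean)
  G2 <- G[ok]
  if (length(unique(G2)) < 2)
    return(structure(list(snp_id = snp_id, beta = NA_real_, se = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          n = sum(ok), df = NA_integer_, untestable = TRUE),
                     class = "assoc_result"))
  X <- if (model == 2) cbind(G = G2, pair_mean = pair_mean[ok])
       else cbind(G = G2)
  fit <- .ols(prepared[ok], X, which = 1L)
  structure(c(list(snp_id = snp_id), fit, list(untestable = FALSE)),
            class = "assoc_result")
}

#' Deviation regression model (DRM) vQTL test
#'
#' Population-based comparator: absolute deviations of the phenotype from
#' its genotype-group median (or mean) are regressed on genotype; the slope
#' indexes variance heterogeneity across genotype groups.
#'
#' @param y Phenotype vector for unrelated individuals.
#' @param G Genotype vector; dosages are rounded to hard calls for grouping
#'   while the regression itself uses the supplied values.
#' @param center `"median"` (default, the Marderstein formulation) or
#'   `"mean"`.
#' @param min_group_n Genotype groups smaller than this are excluded.
#' @param snp_id Optional identifier carried into the result.
#' @return An `assoc_result` list as in [mz_diff_test()].
#' @examples
#' drm_test(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 2, 2, 2))$beta  # 0
#' @export
drm_test <- function(y, G, center = c("median", "mean"), min_group_n = 1L,
                     snp_id = NA_character_) {
  center <- match.arg(center)
  if (length(y) != length(G)) stop("lengths of inputs differ")
  ok <- is.finite(y) & is.finite(G)
  y <- y[ok]; G <- G[ok]
  grp <- as.integer(round(G))
  counts <- table(grp)
  good_groups <- names(counts)[counts >= min_group_n]
  use <- as.character(grp) %in% good_groups
  y <- y[use]; G <- G[use]; grp <- grp[use]
  if (length(unique(grp)) < 2)
    return(structure(list(snp_id = snp_id, beta = NA_real_, se = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          n = length(y), df = NA_integer_, untestable = TRUE),
                     class = "assoc_result"))
  fun <- if (center == "median") stats::median else mean
  ug <- sort(unique(grp))
  ctr <- vapply(ug, function(g) fun(y[grp == g]), numeric(1))
  d <- abs(y - ctr[match(grp, ug)])
  fit <- .ols(as.numeric(d), cbind(G = G), which = 1L)
  structure(c(list(snp_id = snp_id), fit, list(untestable = FALSE)),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("Association result: untestable (monomorphic genotype)\n")
  } else {
    cat(sprintf("Association result%s: beta = %.4g (se %.4g), p = %.3g, n = %d\n",
                if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
                x$beta, x$se, x$p, x$n))
  }
  invisible(x)
}

#' Sign-test concordance between two sets of association results
#'
#' Compares effect directions of two summary-statistic tables (e.g. model 2
#' or 3 versus the primary model 1) on their shared SNPs: fraction of
#' matching signs with an exact binomial test against 0.5, plus Spearman
#' rank correlations of the effect sizes and of -log10(p).
#'
#' @param results_a,results_b Data frames with columns `snp` (or `snp_id`),
#'   `beta` and `p`.
#' @return List with `n_shared`, `concordance`, `binom_p`, `cor_beta`,
#'   `cor_logp`.
#' @export
sign_concordance_test <- function(results_a, results_b) {
  key <- function(d) if ("snp" %in% names(d)) d$snp else d$snp_id
  a <- results_a[!duplicated(key(results_a)), ]
  b <- results_b[!duplicated(key(results_b)), ]
  shared <- intersect(key(a), key(b))
  if (length(shared) == 0) stop("no shared SNPs between the two tables")
  a <- a[match(shared, key(a)), ]
  b <- b[match(shared, key(b)), ]
  match_sign <- sign(a$beta) == sign(b$beta)
  k <- sum(match_sign)
  n <- length(shared)
  list(n_shared = n,
       concordance = k / n,
       binom_p = stats::binom.test(k, n, p = 0.5)$p.value,
       cor_beta = stats::cor(a$beta, b$beta, method = "spearman"),
       cor_logp = stats::cor(-log10(a$p), -log10(b$p), method = "spearman"))
}
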