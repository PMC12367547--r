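#' Construct a genotype source
#'
#' Container consumed by [run_gwas()]: per-variant metadata plus a variants
#' x samples matrix of genotype values (hard calls or dosages in \[0, 2\];
#' `NA` for missing).
#'
#' @param variants Data frame with `id`, `chr`, `pos`, `A1` (effect allele),
#'   `A2`, `info`.
#' @param geno Numeric matrix, one row per variant, one column per sample.
#' @param samples Character vector of sample identifiers (matched against
#'   the phenotype table's `pair_id`).
#' @return A `genotype_source` object.
#' @export
genotype_source <- function(variants, geno, samples) {
  stopifnot(nrow(variants) == nrow(geno), length(samples) == ncol(geno))
  need <- c("id", "chr", "pos", "A1", "A2", "info")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  geno <- as.matrix(geno)
  colnames(geno) <- samples
  structure(list(variants = variants, geno = geno, samples = samples),
            class = "genotype_source")
}

#' @export
print.genotype_source <- function(x, ...) {
  cat(sprintf("Genotype source: %d variants x %d samples\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Run a vQTL GWAS over a genotype source
#'
#' Applies the selected per-SNP test across all variants that pass the
#' variant-level filters, on the samples shared between the genotype source
#' and the phenotype table. Missing genotypes are dropped pairwise per
#' variant. The effect-allele frequency is computed from the analysed
#' samples (`mean(dosage)/2`).
#'
#' @param source A [genotype_source()].
#' @param prepared Data frame from [prepare_phenotype()] (columns `pair_id`,
#'   `prepared`, optionally `pair_mean`), or any table with a phenotype
#'   column named `prepared` keyed by `pair_id`.
#' @param test `"mz_diff"` or `"drm"`.
#' @param model MZ-differences model variant (1, 2 or 3); model 2 requires a
#'   `pair_mean` column.
#' @param maf_min,info_min,callrate_min Variant filters.
#' @return Summary-statistic data frame (`snp`, `chr`, `pos`, `A1`, `A2`,
#'   `eaf`, `beta`, `se`, `p`, `n`, `info`) with attribute `filter_log`
#'   (named counts of variants removed per rule; output rows plus log counts
#'   equal the input variant count).
#' @export
run_gwas <- function(source, prepared, test = c("mz_diff", "drm"),
                     model = 1, maf_min = 0.01, info_min = 0,
                     callrate_min = 0.95) {
  test <- match.arg(test)
  stopifnot(inherits(source, "genotype_source"))
  ids <- intersect(source$samples, prepared$pair_id)
  if (length(ids) == 0)
    stop("no overlap between genotype samples (", length(source$samples),
         ") and phenotype ids (", nrow(prepared), ")")
  geno <- source$geno[, match(ids, source$samples), drop = FALSE]
  ph <- prepared[match(ids, prepared$pair_id), ]
  y <- ph$prepared
  pair_mean <- ph$pair_mean

  nv <- nrow(geno)
  log_counts <- c(info_below_min = 0L, callrate_below_min = 0L,
                  maf_below_min = 0L, monomorphic = 0L)
  rows <- vector("list", nv)
  for (v in seq_len(nv)) {
    g <- geno[v, ]
    info_v <- source$variants$info[v]
    if (!is.na(info_v) && info_v < info_min) {
      log_counts["info_below_min"] <- log_counts["info_below_min"] + 1L
      next
    }
    ok <- !is.na(g) & !is.na(y)
    if (sum(!is.na(g)) / length(g) < callrate_min) {
      log_counts["callrate_below_min"] <- log_counts["callrate_below_min"] + 1L
      next
    }
    eaf <- mean(g[ok]) / 2
    if (min(eaf, 1 - eaf) < maf_min) {
      log_counts["maf_below_min"] <- log_counts["maf_below_min"] + 1L
      next
    }
    res <- if (test == "mz_diff")
      mz_diff_test(y[ok], g[ok], model = model, pair_mean = pair_mean[ok])
    else drm_test(y[ok], g[ok])
    if (isTRUE(res$untestable)) {
      log_counts["monomorphic"] <- log_counts["monomorphic"] + 1L
      next
    }
    rows[[v]] <- data.frame(snp = source$variants$id[v],
                            chr = source$variants$chr[v],
                            pos = source$variants$pos[v],
                            A1 = source$variants$A1[v],
                            A2 = source$variants$A2[v],
                            eaf = eaf, beta = res$beta, se = res$se,
                            p = res$p, n = res$n, info = info_v,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("zero variants passed the filters")
  rownames(out) <- NULL
  attr(out, "filter_log") <- log_counts
  out
}

#' Simulate a multi-variant GWAS study
#'
#' Builds a twin cohort together with a genotype matrix of `n_variants`
#' independent variants (allele frequencies uniform over `maf_range`). One
#' variant may be designated causal: it then follows the generative model of
#' [simulate_twin_cohort()] with `params`, and all other variants are null.
#'
#' @param params A [sim_params()] object (drives the causal variant and the
#'   phenotype).
#' @param n_variants Number of variants.
#' @param causal_index Index of the causal variant in `1:n_variants`, or
#'   `NULL` for a fully null study (the phenotype is then driven by an
#'   unobserved locus with the same parameters).
#' @param maf_range Allele-frequency range for the null variants.
#' @return List with `source` (a [genotype_source()]; `info = 1` throughout)
#'   and `cohort` (a `twin_cohort` with covariates).
#' @export
simulate_gwas_study <- function(params, n_variants = 100,
                                causal_index = NULL,
                                maf_range = c(0.05, 0.5)) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    prm <- params; prm$seed <- NULL
    cohort <- simulate_twin_cohort(prm, covariates = TRUE)
    n <- params$n_pairs
    freqs <- stats::runif(n_variants, maf_range[1], maf_range[2])
    geno <- matrix(stats::rbinom(n_variants * n, 2L, rep(freqs, n)),
                   nrow = n_variants)
    if (!is.null(causal_index)) {
      stopifnot(causal_index >= 1, causal_index <= n_variants)
      geno[causal_index, ] <- cohort$G
      freqs[causal_index] <- params$p
    }
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, n_variants, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(bases, a), 1L), "")
    variants <- data.frame(id = sprintf("snp%04d", seq_len(n_variants)),
                           chr = 1L, pos = seq_len(n_variants) * 1000L,
                           A1 = a1, A2 = a2, info = 1,
                           stringsAsFactors = FALSE)
    list(source = genotype_source(variants, geno, cohort$pair_id),
         cohort = cohort)
  })
}
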