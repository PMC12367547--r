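#' EasyQC-style quality control of GWAS summary statistics
#'
#' Applies the study-level filters in a fixed order and harmonizes alleles
#' against a reference table:
#' \enumerate{
#'   \item rows with missing `beta`, `se`, `p` or `info` (or `se <= 0`);
#'   \item indels / non-ACGT alleles;
#'   \item minor allele frequency below `maf_min`;
#'   \item imputation quality below `info_min`;
#'   \item monomorphic variants (`eaf` 0 or 1, or identical alleles);
#'   \item variants absent from the reference at `chr:pos`;
#'   \item allele harmonization: direct and strand-flipped matches kept;
#'     swapped matches get `beta` negated and `eaf` complemented;
#'     palindromic (A/T, C/G) variants are aligned by frequency when both
#'     study and reference `eaf` are at least `palindromic_margin` away from
#'     0.5, otherwise dropped; non-matching allele pairs dropped;
#'   \item position duplicates: only the row with the largest `n` is kept.
#' }
#' A `cptid` (`chr:pos:A1:A2`, post-harmonization) is added.
#'
#' @param stats Data frame with columns `snp`, `chr`, `pos`, `A1`, `A2`,
#'   `eaf`, `beta`, `se`, `p`, `n`, `info`.
#' @param reference Data frame keyed by `chr`, `pos` with `ref_A1`, `ref_A2`,
#'   `ref_eaf` (frequency of `ref_A1`).
#' @param maf_min Minimum minor allele frequency (0.01).
#' @param info_min Minimum imputation quality (0.5).
#' @param palindromic_margin Minimum |eaf - 0.5| for frequency-resolving
#'   palindromic variants (0.08).
#' @return List with `stats` (the filtered, harmonized table) and `report`
#'   (data frame of rules and rows removed, in application order).
#' @export
qc_summary_stats <- function(stats, reference, maf_min = 0.01,
                             info_min = 0.5, palindromic_margin = 0.08) {
  required <- c("snp", "chr", "pos", "A1", "A2", "eaf", "beta", "se", "p",
                "n", "info")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  ref_required <- c("chr", "pos", "ref_A1", "ref_A2", "ref_eaf")
  if (!all(ref_required %in% names(reference)))
    stop("reference must carry columns ",
         paste(ref_required, collapse = ", "))

  report <- data.frame(rule = character(), removed = integer(),
                       stringsAsFactors = FALSE)
  note <- function(rule, n_removed) {
    report <<- rbind(report, data.frame(rule = rule, removed = n_removed))
  }
  s <- stats
  s$A1 <- toupper(s$A1); s$A2 <- toupper(s$A2)

  keep <- !(is.na(s$beta) | is.na(s$se) | is.na(s$p) | is.na(s$info) |
              s$se <= 0)
  note("missing_beta_se_p_info", sum(!keep)); s <- s[keep, ]

  bases <- c("A", "C", "G", "T")
  keep <- s$A1 %in% bases & s$A2 %in% bases
  note("indel_or_nonacgt", sum(!keep)); s <- s[keep, ]

  maf <- pmin(s$eaf, 1 - s$eaf)
  keep <- !is.na(maf) & maf >= maf_min
  note("maf_below_min", sum(!keep)); s <- s[keep, ]

  keep <- s$info >= info_min
  note("info_below_min", sum(!keep)); s <- s[keep, ]

  keep <- s$eaf > 0 & s$eaf < 1 & s$A1 != s$A2
  note("monomorphic", sum(!keep)); s <- s[keep, ]

  ref_key <- paste(reference$chr, reference$pos, sep = ":")
  idx <- match(paste(s$chr, s$pos, sep = ":"), ref_key)
  keep <- !is.na(idx)
  note("not_in_reference", sum(!keep)); s <- s[keep, ]; idx <- idx[keep]

  rA1 <- toupper(reference$ref_A1[idx]); rA2 <- toupper(reference$ref_A2[idx])
  r_eaf <- reference$ref_eaf[idx]
  pal <- .is_palindromic(s$A1, s$A2)
  direct <- s$A1 == rA1 & s$A2 == rA2
  swapped <- s$A1 == rA2 & s$A2 == rA1
  flipped <- .complement_allele(s$A1) == rA1 & .complement_allele(s$A2) == rA2
  flip_swap <- .complement_allele(s$A1) == rA2 & .complement_allele(s$A2) == rA1

  action <- rep(NA_character_, nrow(s))
  action[flip_swap & !pal] <- "swap"
  action[flipped & !pal] <- "keep"
  action[swapped & !pal] <- "swap"
  action[direct & !pal] <- "keep"
  # palindromic: orientation by frequency when informative on both sides
  pal_match <- pal & (direct | swapped | flipped | flip_swap)
  informative <- pal_match & abs(s$eaf - 0.5) > palindromic_margin &
    abs(r_eaf - 0.5) > palindromic_margin
  informative[is.na(informative)] <- FALSE
  same_side <- sign(s$eaf - 0.5) == sign(r_eaf - 0.5)
  same_side[is.na(same_side)] <- FALSE
  action[informative & same_side] <- "keep"
  action[informative & !same_side] <- "swap"
  n_pal_drop <- sum(pal_match & is.na(action))
  n_mismatch <- sum(is.na(action)) - n_pal_drop
  note("allele_mismatch", n_mismatch)
  note("palindromic_ambiguous", n_pal_drop)

  do_swap <- !is.na(action) & action == "swap"
  s$beta[do_swap] <- -s$beta[do_swap]
  s$eaf[do_swap] <- 1 - s$eaf[do_swap]
  s$A1 <- rA1; s$A2 <- rA2
  s <- s[!is.na(action), ]

  # position duplicates (incl. potential tri-allelics): keep largest n
  ord <- order(s$chr, s$pos, -s$n)
  s <- s[ord, ]
  dup <- duplicated(paste(s$chr, s$pos, sep = ":"))
  note("duplicate_position", sum(dup)); s <- s[!dup, ]

  s$cptid <- paste(s$chr, s$pos, s$A1, s$A2, sep = ":")
  rownames(s) <- NULL
  list(stats = s, report = report)
}

#' Genomic inflation factor from the median p-value
#'
#' `lambda_median`: the median of the 1-df chi-square quantiles implied by
#' the p-values, divided by the null chi-square median (0.4549364).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return The inflation factor; 1 under the null.
#' @examples
#' lambda_median(0.5)  # exactly 1
#' @export
lambda_median <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' METAL-style fixed-effect pooling of per-study summary statistics that have
#' already been QC'd and harmonized to a common reference: per SNP,
#' `w_i = 1/se_i^2`, `beta = sum(w_i b_i) / sum(w_i)`,
#' `se = sqrt(1/sum(w_i))`, `z = beta/se`, two-sided normal p. The output
#' carries a per-study direction string (`+`, `-`, `?` for missing, in input
#' order), the sample-size-weighted mean effect-allele frequency, Cochran's
#' Q heterogeneity statistic (reported, not used as a filter) and total n.
#'
#' @param studies List of QC'd summary-statistic data frames (columns as in
#'   [qc_summary_stats()] output; keyed by `cptid` if present, else `snp`).
#' @return Data frame with `snp`, `chr`, `pos`, `A1`, `A2`, `eaf_avg`,
#'   `beta`, `se`, `z`, `p`, `n_total`, `n_studies`, `direction`, `Q`,
#'   `Q_df`, `Q_p`.
#' @export
ivw_meta <- function(studies) {
  if (!is.list(studies) || length(studies) == 0)
    stop("`studies` must be a non-empty list of summary-statistic tables")
  key_of <- function(d) if ("cptid" %in% names(d)) d$cptid else d$snp
  n_stud <- length(studies)
  all_keys <- unique(unlist(lapply(studies, key_of)))

  # consistency of allele pairs across studies
  allele_tab <- new.env(parent = emptyenv())
  conflicted <- character()
  for (d in studies) {
    k <- key_of(d)
    pair <- paste(toupper(d$A1), toupper(d$A2))
    for (i in seq_along(k)) {
      prev <- allele_tab[[k[i]]]
      if (is.null(prev)) allele_tab[[k[i]]] <- pair[i]
      else if (prev != pair[i]) conflicted <- c(conflicted, k[i])
    }
  }
  if (length(conflicted) > 0) {
    conflicted <- unique(conflicted)
    message(length(conflicted),
            " SNP(s) dropped for conflicting allele pairs across studies")
    all_keys <- setdiff(all_keys, conflicted)
  }

  m <- length(all_keys)
  sw <- swb <- swb2 <- n_tot <- eafn <- nn <- numeric(m)
  k_count <- integer(m)
  dir_mat <- matrix("?", nrow = m, ncol = n_stud)
  meta_a1 <- meta_a2 <- meta_chr <- meta_pos <- meta_snp <- rep(NA, m)
  for (j in seq_len(n_stud)) {
    d <- studies[[j]]
    idx <- match(key_of(d), all_keys)
    ok <- !is.na(idx) & !is.na(d$beta) & !is.na(d$se) & d$se > 0
    idx <- idx[ok]; dd <- d[ok, ]
    w <- 1 / dd$se^2
    sw[idx] <- sw[idx] + w
    swb[idx] <- swb[idx] + w * dd$beta
    swb2[idx] <- swb2[idx] + w * dd$beta^2
    n_tot[idx] <- n_tot[idx] + dd$n
    eafn[idx] <- eafn[idx] + dd$eaf * dd$n
    nn[idx] <- nn[idx] + dd$n
    k_count[idx] <- k_count[idx] + 1L
    dir_mat[cbind(idx, j)] <- ifelse(dd$beta >= 0, "+", "-")
    newi <- is.na(meta_a1[idx])
    meta_a1[idx[newi]] <- dd$A1[newi]; meta_a2[idx[newi]] <- dd$A2[newi]
    meta_chr[idx[newi]] <- dd$chr[newi]; meta_pos[idx[newi]] <- dd$pos[newi]
    meta_snp[idx[newi]] <- dd$snp[newi]
  }
  beta <- swb / sw
  se <- sqrt(1 / sw)
  z <- beta / se
  Q <- swb2 - swb^2 / sw    # sum w (b - beta)^2
  Q_df <- pmax(k_count - 1L, 0L)
  Q_p <- ifelse(Q_df > 0, stats::pchisq(Q, Q_df, lower.tail = FALSE), NA)
  out <- data.frame(snp = meta_snp, chr = meta_chr, pos = meta_pos,
                    A1 = meta_a1, A2 = meta_a2,
                    eaf_avg = eafn / nn, beta = beta, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    n_total = n_tot, n_studies = k_count,
                    direction = apply(dir_mat, 1, paste, collapse = ""),
                    Q = Q, Q_df = Q_df, Q_p = Q_p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter meta-analysis results by study availability
#'
#' Keeps SNPs observed (non-`?` direction) in at least `min_prop` of the
#' contributing studies.
#'
#' @param meta Output of [ivw_meta()].
#' @param min_prop Minimum proportion of studies (0.5 by default).
#' @return The filtered meta table.
#' @export
availability_filter <- function(meta, min_prop = 0.5) {
  n_stud <- nchar(meta$direction)
  observed <- nchar(gsub("\\?", "", meta$direction))
  meta[observed / n_stud >= min_prop, , drop = FALSE]
}

#' Genome-wide significant hits
#'
#' @param meta Meta-analysis table with a `p` column.
#' @param threshold Significance threshold (5e-8).
#' @return Rows with `p < threshold`, sorted by `p`.
#' @export
genome_wide_hits <- function(meta, threshold = 5e-8) {
  hits <- meta[!is.na(meta$p) & meta$p < threshold, , drop = FALSE]
  hits[order(hits$p), , drop = FALSE]
}
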