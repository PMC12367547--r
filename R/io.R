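#' Read and write summary-statistic tables
#'
#' The package's summary-statistic dialect is a tab-separated table with a
#' header row (`snp`, `chr`, `pos`, `A1`, `A2`, `eaf`, `beta`, `se`, `p`,
#' `n`, `info`, plus any extra columns such as `cptid`). Readers are
#' gzip-transparent.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return A data frame.
#' @export
read_sumstats <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_sumstats
#' @param stats Summary-statistic data frame.
#' @export
write_sumstats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' Write a twin cohort (or population cohort) to TSV
#'
#' @param cohort A `twin_cohort` or `population_cohort`.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  tab <- if (inherits(cohort, "twin_cohort")) as.data.frame(cohort)
         else data.frame(id = cohort$id, G = cohort$G, y = cohort$y)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read a twin cohort from TSV
#'
#' Expects columns `pair_id`, `G`, `yA`, `yB`; any remaining columns are
#' treated as covariates.
#'
#' @param path Input path.
#' @return A `twin_cohort` (without generative parameters).
#' @export
read_cohort_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("pair_id", "G", "yA", "yB")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tab), need)
  structure(list(pair_id = as.character(tab$pair_id), G = tab$G, z = NULL,
                 yA = tab$yA, yB = tab$yB,
                 covariates = if (length(extra) > 0)
                   tab[, extra, drop = FALSE] else NULL,
                 params = NULL),
            class = "twin_cohort")
}

#' Read genotypes from a variants-by-samples TSV matrix
#'
#' First six columns `id`, `chr`, `pos`, `A1`, `A2`, `info`; remaining
#' columns are per-sample genotype values (hard calls or dosages).
#'
#' @param path Input path (gzip-transparent).
#' @return A [genotype_source()].
#' @export
read_genotypes_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta_cols <- c("id", "chr", "pos", "A1", "A2", "info")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss) > 0)
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  samples <- setdiff(names(tab), meta_cols)
  genotype_source(tab[, meta_cols], as.matrix(tab[, samples, drop = FALSE]),
                  samples)
}

#' @rdname read_genotypes_tsv
#' @param source A [genotype_source()].
#' @export
write_genotypes_tsv <- function(source, path) {
  tab <- cbind(source$variants[, c("id", "chr", "pos", "A1", "A2", "info")],
               as.data.frame(source$geno))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Export a genotype source as VCF
#'
#' One record per variant with `GT` (hard call, effect-allele count as ALT
#' dosage) and `DS` (dosage) fields. REF is the non-effect allele `A2`, ALT
#' the effect allele `A1`, so `DS` counts effect alleles. Missing genotypes
#' become `./.` with DS `.`.
#'
#' @param source A [genotype_source()].
#' @param path Output path (plain text; use [read_genotypes_vcf()] to read
#'   back).
#' @export
write_genotypes_vcf <- function(source, path) {
  v <- source$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mzvqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Effect allele dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", source$samples), collapse = "\t")),
             con)
  gt_code <- function(g) {
    hard <- round(g)
    out <- rep("./.:.", length(g))
    ok <- !is.na(g)
    out[ok] <- paste0(c("0/0", "0/1", "1/1")[hard[ok] + 1L], ":",
                      format(g[ok], trim = TRUE))
    out
  }
  for (i in seq_len(nrow(v))) {
    fields <- gt_code(source$geno[i, ])
    writeLines(paste(c(v$chr[i], v$pos[i], v$id[i], v$A2[i], v$A1[i], ".",
                       "PASS", paste0("INFO_SCORE=", v$info[i]), "GT:DS",
                       fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF via \pkg{vcfR} and returns a [genotype_source()]. The `DS`
#' (dosage) FORMAT field is used when present, otherwise dosages are counted
#' from `GT` (number of ALT alleles). The effect allele `A1` is ALT, `A2` is
#' REF; `info` is taken from an `INFO_SCORE`, `INFO` or `R2` INFO key when
#' present, else 1.
#'
#' @param path VCF path (gzip-transparent).
#' @return A [genotype_source()].
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    geno <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    geno <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
  }
  info_raw <- vcfR::extract.info(vcf, element = "INFO_SCORE")
  if (all(is.na(info_raw))) info_raw <- vcfR::extract.info(vcf, element = "R2")
  info <- suppressWarnings(as.numeric(info_raw))
  info[is.na(info)] <- 1
  samples <- colnames(vcf@gt)[-1]
  variants <- data.frame(id = fix$ID, chr = fix$CHROM,
                         pos = as.integer(fix$POS),
                         A1 = fix$ALT, A2 = fix$REF, info = info,
                         stringsAsFactors = FALSE)
  genotype_source(variants, unname(as.matrix(geno)), samples)
}
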