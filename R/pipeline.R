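# End-to-end orchestration: simulate -> prep -> gwas -> qc -> meta -> hits.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(n_studies = 2L, n_pairs = 2000L, n_variants = 200L,
                    p = 0.3, beta1 = 0, beta2 = 0, h2 = 0.5,
                    causal_index = NULL),
    prep = list(model = 1L),
    gwas = list(test = "mz_diff", maf_min = 0.01, info_min = 0,
                callrate_min = 0.95),
    qc = list(maf_min = 0.01, info_min = 0.5),
    meta = list(min_prop = 0.5),
    hits = list(threshold = 5e-8)
  )
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML files mirroring the argument blocks of the
#' pipeline stages (`seed`, `simulate`, `prep`, `gwas`, `qc`, `meta`,
#' `hits`). Unknown keys are rejected; omitted keys take the defaults shown
#' by `read_pipeline_config(NULL)`.
#'
#' @param path YAML file path, or `NULL` for the default configuration.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- .pipeline_defaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (blk in setdiff(names(defaults), "seed")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
      if (length(bad) > 0)
        stop("unknown key(s) in `", blk, "`: ", paste(bad, collapse = ", "))
      defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    }
  }
  if (!is.null(cfg$seed)) defaults$seed <- cfg$seed
  structure(defaults, class = "pipeline_config")
}

#' Run the full MZ-differences GWAS pipeline on simulated studies
#'
#' Executes simulate -> prepare phenotype -> GWAS -> summary-statistic QC ->
#' IVW meta-analysis -> availability filter -> genome-wide hits, writing
#' every stage's table as TSV into `out_dir` together with the resolved
#' configuration, a log (variant counts, per-rule filter tallies,
#' lambda_median per study and for the meta-analysis) and a manifest of all
#' artifacts with md5 content hashes. Reference allele frequencies for QC
#' harmonization are taken from the simulated truth.
#'
#' @param config A `pipeline_config` ([read_pipeline_config()]), a YAML
#'   path, or `NULL` for defaults.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `meta`, `hits`, `lambda_meta`,
#'   `lambda_study`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  if (is.null(config) || is.character(config))
    config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(as.data.frame(tab), path, sep = "\t")
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- "config"
  result <- tryCatch({
    yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
    artifacts <- c(artifacts, file.path(out_dir, "config_resolved.yaml"))

    stage <- "simulate"
    sm <- config$simulate
    seeds <- .derive_seeds(config$seed, sm$n_studies)
    studies <- vector("list", sm$n_studies)
    for (s in seq_len(sm$n_studies)) {
      prm <- sim_params(p = sm$p, beta1 = sm$beta1, beta2 = sm$beta2,
                        sigma2_g = sm$h2, n_pairs = sm$n_pairs,
                        seed = seeds[[s]])
      studies[[s]] <- simulate_gwas_study(prm, n_variants = sm$n_variants,
                                          causal_index = sm$causal_index)
      say("study %d: simulated %d variants x %d pairs", s, sm$n_variants,
          sm$n_pairs)
    }

    stage <- "prep"
    prepped <- lapply(studies, function(st)
      prepare_phenotype(st$cohort, model = config$prep$model))

    stage <- "gwas"
    sumstats <- vector("list", sm$n_studies)
    for (s in seq_len(sm$n_studies)) {
      ss <- run_gwas(studies[[s]]$source, prepped[[s]],
                     test = config$gwas$test, model = config$prep$model,
                     maf_min = config$gwas$maf_min,
                     info_min = config$gwas$info_min,
                     callrate_min = config$gwas$callrate_min)
      fl <- attr(ss, "filter_log")
      say("study %d GWAS: %d variants tested; filtered: %s", s, nrow(ss),
          paste(names(fl), fl, sep = "=", collapse = ", "))
      say("study %d lambda_median = %.3f", s, lambda_median(ss$p))
      emit(ss, sprintf("study%d_sumstats.tsv", s))
      sumstats[[s]] <- ss
    }

    stage <- "qc"
    # reference: simulated truth of study 1 (shared variant panel)
    ref_src <- studies[[1]]$source$variants
    reference <- data.frame(chr = ref_src$chr, pos = ref_src$pos,
                            ref_A1 = ref_src$A1, ref_A2 = ref_src$A2,
                            ref_eaf = sumstats[[1]]$eaf[
                              match(ref_src$id, sumstats[[1]]$snp)])
    reference$ref_eaf[is.na(reference$ref_eaf)] <- 0.5
    cleaned <- vector("list", sm$n_studies)
    for (s in seq_len(sm$n_studies)) {
      qcres <- qc_summary_stats(sumstats[[s]], reference,
                                maf_min = config$qc$maf_min,
                                info_min = config$qc$info_min)
      say("study %d QC: %d rows kept; removed: %s", s, nrow(qcres$stats),
          paste(qcres$report$rule, qcres$report$removed, sep = "=",
                collapse = ", "))
      emit(qcres$stats, sprintf("study%d_sumstats_qc.tsv", s))
      cleaned[[s]] <- qcres$stats
    }

    stage <- "meta"
    meta <- ivw_meta(cleaned)
    meta <- availability_filter(meta, min_prop = config$meta$min_prop)
    say("meta-analysis: %d SNPs after availability filter; lambda_median = %.3f",
        nrow(meta), lambda_median(meta$p))
    emit(meta, "meta.tsv")

    stage <- "hits"
    hits <- genome_wide_hits(meta, threshold = config$hits$threshold)
    say("%d genome-wide hit(s) at p < %g", nrow(hits),
        config$hits$threshold)
    emit(hits, "hits.tsv")

    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    artifacts <- c(artifacts, file.path(out_dir, "pipeline.log"))
    manifest <- data.frame(artifact = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           stringsAsFactors = FALSE)
    data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t")
    list(meta = meta, hits = hits,
         lambda_meta = lambda_median(meta$p),
         lambda_study = vapply(cleaned, function(d) lambda_median(d$p),
                               numeric(1)),
         manifest = manifest)
  }, error = function(e) {
    writeLines(c(log_lines, paste("FAILED at stage:", stage),
                 conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
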