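make_reference <- function() {
  data.frame(chr = 1, pos = c(100, 200, 300, 400, 500, 600),
             ref_A1 = c("A", "C", "G", "T", "A", "C"),
             ref_A2 = c("G", "T", "A", "C", "G", "A"),
             ref_eaf = c(0.3, 0.4, 0.2, 0.25, 0.35, 0.45))
}

test_that("each QC rule fires once on a constructed toy table", {
  ref <- make_reference()
  tab <- rbind(
    sumstat_row("clean1", pos = 100, A1 = "A", A2 = "G", eaf = 0.3),
    sumstat_row("clean2", pos = 200, A1 = "C", A2 = "T", eaf = 0.4),
    sumstat_row("lowmaf", pos = 300, A1 = "G", A2 = "A", eaf = 0.005),
    sumstat_row("lowinfo", pos = 400, A1 = "T", A2 = "C", eaf = 0.25,
                info = 0.4),
    sumstat_row("indel", pos = 500, A1 = "AT", A2 = "A", eaf = 0.35),
    sumstat_row("mismatch", pos = 600, A1 = "C", A2 = "G", eaf = 0.45)
  )
  res <- qc_summary_stats(tab, ref)
  expect_equal(nrow(res$stats), 2)
  expect_setequal(res$stats$snp, c("clean1", "clean2"))
  rep <- setNames(res$report$removed, res$report$rule)
  expect_equal(unname(rep["maf_below_min"]), 1)
  expect_equal(unname(rep["info_below_min"]), 1)
  expect_equal(unname(rep["indel_or_nonacgt"]), 1)
  # C/G at pos 600 is palindromic and the reference carries C/A there
  expect_equal(unname(rep["allele_mismatch"] + rep["palindromic_ambiguous"]),
               1)
  expect_true(all(res$stats$cptid == paste(res$stats$chr, res$stats$pos,
                                           res$stats$A1, res$stats$A2,
                                           sep = ":")))
})

test_that("swapped alleles are harmonized with sign flip and eaf complement", {
  ref <- make_reference()
  tab <- sumstat_row("swapped", pos = 100, A1 = "G", A2 = "A", eaf = 0.7,
                     beta = 0.12)
  res <- qc_summary_stats(tab, ref)
  expect_equal(res$stats$beta, -0.12)
  expect_equal(res$stats$eaf, 0.3)
  expect_equal(res$stats$A1, "A")
  expect_equal(res$stats$A2, "G")
})

test_that("duplicate positions keep the largest sample and QC is idempotent", {
  ref <- make_reference()
  tab <- rbind(
    sumstat_row("dupA", pos = 100, A1 = "A", A2 = "G", eaf = 0.3, n = 500),
    sumstat_row("dupB", pos = 100, A1 = "A", A2 = "G", eaf = 0.31, n = 900),
    sumstat_row("keep", pos = 200, A1 = "C", A2 = "T", eaf = 0.4)
  )
  res <- qc_summary_stats(tab, ref)
  expect_equal(nrow(res$stats), 2)
  expect_true("dupB" %in% res$stats$snp)
  expect_false("dupA" %in% res$stats$snp)
  # idempotence on a larger random table
  set.seed(51)
  n <- 200
  big_ref <- data.frame(chr = 1, pos = seq_len(n) * 10,
                        ref_A1 = sample(c("A", "C"), n, TRUE),
                        ref_A2 = "G", ref_eaf = runif(n, 0.05, 0.95))
  big <- data.frame(snp = paste0("v", seq_len(n)), chr = 1,
                    pos = seq_len(n) * 10, A1 = big_ref$ref_A1, A2 = "G",
                    eaf = runif(n, 0.001, 0.999), beta = rnorm(n),
                    se = runif(n, 0.01, 0.1), p = runif(n), n = 1000,
                    info = runif(n, 0.3, 1))
  pass1 <- qc_summary_stats(big, big_ref)
  pass2 <- qc_summary_stats(pass1$stats[, names(big)], big_ref)
  expect_equal(nrow(pass2$stats), nrow(pass1$stats))
  expect_equal(sum(pass2$report$removed), 0)
  expect_equal(pass2$stats$beta, pass1$stats$beta)
})

test_that("missing mandatory columns are reported by name", {
  expect_error(qc_summary_stats(data.frame(snp = "a"), make_reference()),
               "chr.*pos")
})

test_that("lambda_median is exact at the null median and scale-equivariant", {
  expect_equal(lambda_median(0.5), 1)
  set.seed(52)
  expect_equal(lambda_median(runif(100000)), 1, tolerance = 0.02)
  # inflated statistics: chi2 * 1.3 => lambda ~ 1.3, vs quantile oracle
  chi <- rchisq(100000, 1) * 1.3
  p_inf <- pchisq(chi, 1, lower.tail = FALSE)
  oracle <- median(chi) / qchisq(0.5, 1)
  got <- lambda_median(p_inf)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(got, 1.3, tolerance = 0.03)
  expect_error(lambda_median(numeric(0)), "no p-values")
})

test_that("IVW meta reproduces identities: single study, equal weights, self-duplication", {
  s1 <- sumstat_row("rs1", pos = 100, A1 = "A", A2 = "G", eaf = 0.3,
                    beta = 0.1, se = 0.1, p = 0.32, n = 1000)
  m1 <- ivw_meta(list(s1))
  expect_equal(m1$beta, 0.1)
  expect_equal(m1$se, 0.1)
  expect_equal(m1$p, 2 * pnorm(-1), tolerance = 1e-12)
  s2 <- s1; s2$beta <- 0.3
  m2 <- ivw_meta(list(s1, s2))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m2$direction, "++")
  dup <- ivw_meta(list(s1, s1))
  expect_equal(dup$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # order invariance up to the direction-string permutation
  s3 <- s1; s3$beta <- -0.05; s3$se <- 0.2
  ab <- ivw_meta(list(s1, s3)); ba <- ivw_meta(list(s3, s1))
  expect_equal(ab$beta, ba$beta, tolerance = 1e-12)
  expect_equal(ab$direction, "+-")
  expect_equal(ba$direction, "-+")
})

test_that("fixed-effect pooling beats any single study in MSE", {
  set.seed(53)
  true_b <- 0.1
  ses <- c(0.05, 0.08, 0.1, 0.12, 0.2)
  nrep <- 300
  err_meta <- numeric(nrep)
  err_single <- matrix(0, nrep, 5)
  for (r in seq_len(nrep)) {
    betas <- rnorm(5, true_b, ses)
    studies <- lapply(1:5, function(i)
      sumstat_row("rs1", pos = 100, A1 = "A", A2 = "G", eaf = 0.3,
                  beta = betas[i], se = ses[i], p = 0.5, n = 1000))
    err_meta[r] <- (ivw_meta(studies)$beta - true_b)^2
    err_single[r, ] <- (betas - true_b)^2
  }
  expect_true(all(mean(err_meta) < colMeans(err_single)))
  # and the pooled estimate matches the closed-form weighted mean
  w <- 1 / ses^2
  expect_equal(ivw_meta(lapply(1:5, function(i)
    sumstat_row("rs1", pos = 100, A1 = "A", A2 = "G", eaf = 0.3,
                beta = ses[i], se = ses[i], p = 0.5, n = 1000)))$beta,
    sum(w * ses) / sum(w), tolerance = 1e-12)
})

test_that("availability filter keys on the direction string", {
  meta <- data.frame(snp = c("a", "b", "c"), p = c(0.1, 0.2, 0.3),
                     direction = c("+++??", "+????", "++---"))
  kept <- availability_filter(meta, 0.5)
  expect_setequal(kept$snp, c("a", "c"))
  expect_equal(nrow(availability_filter(meta, 0)), 3)
})

test_that("genome-wide hit extraction respects the threshold and sorts by p", {
  meta <- data.frame(snp = c("a", "b", "c"),
                     p = c(0.5, 9.93e-9, 3e-10))
  expect_equal(nrow(genome_wide_hits(meta[1, , drop = FALSE])), 0)
  hits <- genome_wide_hits(meta)
  expect_equal(hits$snp, c("c", "b"))
  expect_equal(nrow(genome_wide_hits(meta, threshold = 1)), 3)
})
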