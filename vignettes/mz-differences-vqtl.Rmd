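---
title: "Detecting variance QTLs from MZ twin differences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variance QTLs from MZ twin differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzvqtl)
```

## The scientific problem

Most GWAS target the *mean* of a phenotype. A variance QTL (vQTL) is a
variant associated with the phenotype's *variance* instead — the classic
signature of gene–environment interaction and, more generally, of
genotype-dependent environmental sensitivity. Population-based vQTL tests
compare phenotypic spread across genotype groups in unrelated individuals.
The monozygotic (MZ) twin differences design takes a different route: MZ
twins are genetically identical, so the absolute within-pair difference
`|yA - yB|` is driven entirely by non-shared environment. Regressing that
difference score on genotype asks directly whether an allele makes
genetically identical people diverge — while dynastic effects, epistasis and
gene–environment correlation, which can confound population-based variance
tests, are differenced out.

`mzvqtl` implements the full analysis chain: a generative twin simulator,
phenotype preparation, the MZ-differences test and a population comparator,
a power and false-discovery simulation study, summary-statistic QC and
inverse-variance-weighted (IVW) meta-analysis, and two-sample IVW Mendelian
randomization (MR).

## The generative model

For MZ pair $i$ and twin $t \in \{A, B\}$:

$$y_{i,t} = \alpha + \beta_1 G_i + z_i + v_{i,t} + e_{i,t}$$

* $G_i \sim \mathrm{Binom}(2, p)$ — the shared genotype;
* $\beta_1$ — additive effect per allele (SD units);
* $z_i \sim N(0,\; \sigma^2_g - 2p(1-p)\beta_1^2)$ — the shared residual
  polygenic value, so total additive variance is exactly $\sigma^2_g$
  (the narrow-sense heritability $h^2$ on this unit-variance scale);
* $v_{i,t} \sim N(0,\; \beta_2 G_i)$ — the vQTL term: each effect allele
  adds $\beta_2$ to the within-person environmental variance, drawn
  independently per twin (within-pair divergence comes from $v + e$);
* $e_{i,t} \sim N(0,\; 1 - \sigma^2_g - \sigma^2_v)$ — independent residual.

The marginal variance of $v$ is not pinned down by the defining equations
alone; we take $\sigma^2_v = E[\mathrm{var}(v \mid G)] = 2p\beta_2$ (law of
total variance with $E[G] = 2p$), which makes the unit-variance
decomposition exact. `sim_params()` enforces the feasibility constraints
($0 < p < 1$, $\beta_2 \ge 0$, $\sigma^2_g \ge 2p(1-p)\beta_1^2$,
$\sigma^2_g + \sigma^2_v \le 1$) and every simulator rejects violations by
name. Two useful identities that the tests exploit:

* $\mathrm{var}(y_{A} - y_{B} \mid G) = 2(\beta_2 G + \sigma^2_e)$, so
  $E\lvert y_A - y_B \rvert = \sqrt{2/\pi}\sqrt{2(\beta_2 G + \sigma^2_e)}$
  (folded normal);
* $\mathrm{cor}(y_A, y_B) = \sigma^2_g$ when $\beta_2 = 0$.

The intercept $\alpha$ defaults to 0; nonzero values are supported but play
no role in any analysis (the difference score removes them).

### LD-tagged loci

`simulate_tagged_locus()` builds two loci with equal allele frequency $p$
and haplotype disequilibrium $D = \sqrt{r^2}\,p(1-p)$; genotypes are sums of
two independent haplotypes, so the genotype-level squared correlation equals
the target $r^2$ exactly in expectation (`tagged_locus_r2_exact()`
enumerates the four haplotype frequencies as a check). Equal frequencies at
both loci are the simplest construction that reaches any $r^2 \in [0,1]$;
unequal frequencies would cap the achievable $r^2$.

## Phenotype preparation

The pipeline order is fixed: absolute pair difference → covariate
residualization → standardization → rank-based inverse-normal transform.
Three variants mirror common sensitivity analyses:

* **model 1** (primary): residualize on age, sex and ten genetic principal
  components;
* **model 2**: as model 1, and carry the within-pair mean $(y_A + y_B)/2$
  into the association model as a covariate — a probe for whether
  difference associations merely reflect mean associations (at the risk of
  over-correction, since a true vQTL moves both the mean and the variance of
  the difference score);
* **model 3**: drop the principal components (for very small studies where
  ten PCs over-fit).

The inverse-normal transform uses ranks with Blom's offset $c = 3/8$,
$\Phi^{-1}\big((r - c)/(n - 2c + 1)\big)$, average ranks for ties — the most
common GWAS convention; the offset is an argument. The prepared score is
therefore invariant to any affine rescaling of the raw phenotype, and
permuting input rows permutes outputs identically.

Pairs missing either twin's phenotype are excluded (complete-pair rule);
missing-data imputation is deliberately out of scope.

## Association tests

* `mz_diff_test()` — OLS of the prepared score on an intercept and genotype
  (plus the pair mean under model 2). The genotype slope estimates the
  per-allele variance effect $\beta_2$ up to the scale of the transform.
  Inference uses the $t$ reference with $n - k$ df; at GWAS sample sizes
  this is indistinguishable from normal.
* `drm_test()` — the deviation regression model: absolute deviations of the
  phenotype from its genotype-group **median** are regressed on genotype.
  Median centring is the default (robust to mean effects); `center = "mean"`
  is available. Dosage input is rounded to hard calls for grouping only.
* `sign_concordance_test()` — cross-model agreement: shared-SNP sign
  concordance with an exact binomial test, plus Spearman correlations of
  effects and $-\log_{10}p$.

## The power and false-discovery study

`calibrate_beta2()` inverts an analytic power approximation for the DRM
slope. Conditional on $G = g$ the phenotype variance is $c + \beta_2 g$ with
$c = 1 - 2p(1-p)\beta_1^2 - \sigma^2_v$ (note $\sigma^2_g$ cancels — DRM
power does not depend on heritability under this model), giving expected
slope $\sqrt{2/\pi}\,\beta_2 / (2\sqrt{c + 2p\beta_2})$ and slope SE
$\sqrt{(1 - 2/\pi)(c + 2p\beta_2)/(2np(1-p))}$. The two-sided normal power
is bisected to the target; the standard calibration (80% power for DRM in
500,000 unrelated individuals at $p = 0.3$, $\beta_1 = 0$,
$\alpha = 5\times 10^{-8}$) returns $\beta_2 \approx 0.0208$, and simulated
DRM power at that value lands within Monte-Carlo error of 80% (the
acceptance suite verifies this with 500 replicates).

`power_curve()` then compares designs: MZ-differences power across a
heritability grid at 10,000 pairs versus DRM power at a matched 20,000
individuals and at 500,000. Higher $h^2$ shrinks $\sigma^2_e$, so the vQTL
term makes up a larger share of the pair difference and MZ power rises
steeply with heritability, crossing the large-cohort DRM power only around
$h^2 \approx 0.9$; at equal sample sizes the twin design dominates. We use
500 replicates per grid point (binomial SE $\le 0.022$), which keeps the
full study within a few minutes on one core; `reps` is an argument.

`fdr_study()` probes the "phantom vQTL" artefact: an additive-only locus
($\beta_1 = 0.1$, $\beta_2 = 0$, $h^2 = 0.5$, $p = 0.1$) is tagged at
$r^2 \in [0,1]$ and the vQTL tests run at the tag. Within tag-genotype
groups the phenotype is then a *mixture* over causal genotypes, and
$\mathrm{var}(G \mid G^* = g^*) = g^* v_1 + (2 - g^*) v_0$ varies linearly
in $g^*$ — a spurious variance gradient of magnitude $\beta_1^2 (v_1 - v_0)$
that inflates population-based tests. Two consequences the tests assert:

* the MZ-differences test is immune (the within-pair difference never sees
  $\beta_1 G$ or $z$), so its false-positive rate stays nominal across the
  grid;
* DRM inflation vanishes at **both** ends — at $r^2 = 0$ (independence) and
  at $r^2 = 1$ (perfect LD leaves no mixture) — and peaks at intermediate
  LD. With a per-allele effect of $\beta_1 = 0.1$ the inflation is real but
  modest (false-positive rate roughly 0.07–0.09 at $\alpha = 0.05$ with
  500,000 individuals), so the suite asserts *elevation over the MZ test at
  intermediate LD*, not monotone growth in $r^2$, which the generative
  model itself rules out.

Sample sizes for this study are not dictated by the power experiment; we
default to the same desk scale (10,000 pairs; 500,000 individuals) and 500
repeats per grid point. All grid runs derive per-cell seeds from one master
seed, so results are bit-reproducible.

## Summary-statistic QC and meta-analysis

`qc_summary_stats()` applies the standard study-level filters in a fixed,
reported order (missing estimates; indels; MAF < 0.01; info < 0.5;
monomorphic; absent from reference; allele mismatch; ambiguous palindromes;
position duplicates keeping the largest n) and harmonizes alleles to a
reference panel, flipping signs and complementing frequencies for swapped
labels and tolerating strand flips. Palindromic (A/T, C/G) variants are
aligned by allele frequency when both study and reference are at least 0.08
away from 0.5, else dropped. QC output is idempotent: a second pass removes
nothing. `lambda_median()` gives the median-based genomic inflation factor
(median 1-df chi-square quantile over 0.4549364).

`ivw_meta()` is the fixed-effect inverse-variance scheme: weights
$1/se^2$, pooled `beta`, `se = sqrt(1/sum(w))`, normal p, a per-study
direction string (`+`, `-`, `?` in input order), sample-size-weighted mean
allele frequency and Cochran's Q (reported, never filtered on).
`availability_filter()` keeps SNPs observed in at least half the studies
before downstream use, and `genome_wide_hits()` applies the conventional
$5\times10^{-8}$ threshold. Variants whose allele pairs conflict across
studies after harmonization are dropped with a message.

## Mendelian randomization

`mr_harmonize()` joins exposure and outcome tables on chromosome and
position and aligns the outcome effect to the exposure's effect allele
(sign flip on label swap, strand flips tolerated, ambiguous palindromes
dropped). `mr_ivw()` is weighted least squares of outcome on exposure
effects through the origin with weights $1/se_Y^2$ — the fixed-effect IVW
estimator, whose SE matches the scale reported for liability-on-variability
analyses; a multiplicative random-effects SE is available via
`method = "random"`. With one instrument it degrades to the Wald ratio.
Cochran's Q with $n_{snp} - 1$ df quantifies instrument heterogeneity.
`mr_group_difference()` compares two independent IVW estimates (for
example, adults versus children) by the z-test on the difference — for a
two-group contrast this is numerically the same comparison as a
group-by-exposure interaction term. On published effect sizes of 1.58
(se 0.29) versus 0.35 (se 0.35) it gives p = 0.0068, matching the reported
interaction p of 0.008 to its printed precision. Instrument *selection*
(LD clumping) is out of scope; the module consumes a pre-selected list.

`simulate_mr_instruments()` provides the recovery harness: known exposure
effects, outcome effects generated under a known causal slope with exact
SEs. Over replicates the 95% CI covers the truth at its nominal rate, and
heterogeneity p-values are uniform — both asserted in the tests.

## The pipeline and CLI

`run_pipeline()` chains simulate → prep → GWAS → QC → meta → hits over a
YAML configuration (unknown keys rejected; the resolved configuration is
written next to the outputs), logging per-stage variant counts, filter
tallies and inflation factors, and writing a manifest of every artifact
with md5 hashes — two runs with the same seed produce identical manifests.
`inst/cli/mzvqtl.R` exposes each stage as a subcommand; it contains no
computation of its own.

## What the simulations do and do not show

The generator is faithful to the stated model, which is also its limit:
one biallelic locus per phenotype (plus one tag), Hardy–Weinberg genotypes,
normal residuals, no genome-wide LD structure, no dosage uncertainty, no
ascertainment, covariates as pure noise fixtures. Passing tests demonstrate
the statistical machinery — calibration, size, power ordering, robustness
to additive tagging, meta and MR identities — not performance on real
cohort data with population structure, informative missingness or
non-normal phenotypes (the inverse-normal transform blunts, but does not
remove, the last of these). Real summary statistics can be fed to the QC,
meta-analysis and MR modules unchanged through the TSV dialect.

## Numerical choices

* OLS via QR (`lm.fit`); SEs from $n-k$-df residual variance.
* Bisection for calibration to $10^{-4}$ in power.
* Ties in ranks: average; all-identical input is an error, not a guess.
* DRM requires at least two genotype groups (configurable minimum size);
  monomorphic variants are flagged untestable and excluded from outputs,
  never silently zero-filled.
* Per-cell seeds are drawn from the master seed with `sample.int()` below
  $2^{31}$, so every grid cell is independently reproducible.
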