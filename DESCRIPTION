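Package: mzvqtl
Title: Variance-QTL Discovery from Monozygotic Twin Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting variance quantitative trait loci (vQTLs)
    with the monozygotic (MZ) twin differences design. Provides a twin-cohort
    simulator under an explicit generative model with per-allele variance
    inflation, phenotype preparation (absolute pair differences, covariate
    residualization, rank-based inverse-normal transformation), the
    MZ-differences regression test and the population-based deviation
    regression model (DRM) comparator, power and false-discovery simulation
    studies under linkage-disequilibrium tagging, EasyQC-style summary
    statistic quality control with allele harmonization, METAL-style
    inverse-variance-weighted fixed-effect meta-analysis, and two-sample
    inverse-variance-weighted Mendelian randomization of genetic liability
    on phenotypic variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
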