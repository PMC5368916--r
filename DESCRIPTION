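Package: cordews
Title: Two-Cohort Cord-Blood Methylation Array Analysis with Order-Statistic
    Meta-Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for epigenome-wide association analysis of
    Illumina 450K-style methylation data from gestational diabetes (GDM) cord
    blood studies run as two independent cohorts. Implements the probe quality
    filter cascade (beadcount, detection p-value, SNP overlap, sex
    chromosomes), dasen-style between-array quantile normalization of
    methylated/unmethylated intensities, BMIQ beta-mixture quantile dilation
    for type II probe bias, empirical-Bayes moderated t-tests on beta values
    with Benjamini-Hochberg correction, combination of per-probe p-values
    across two cohorts via order statistics of two uniform random variables,
    reference-based cell-type deconvolution by constrained projection,
    pyrosequencing-panel validation statistics (Mann-Whitney tests and
    confounder-adjusted regression), and cohort characteristics tables. A
    synthetic-data module generates two-cohort datasets with planted effects,
    cell mixtures and confounding for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    limma,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
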