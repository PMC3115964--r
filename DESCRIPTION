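Package: methylquant
Title: Statistical Quantification of DNA Methylation Levels from
    Sequencing Tag Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates DNA methylation levels from methylation-sensitive
    restriction-enzyme sequencing (paired MspI/HpaII tag counts,
    "Methyl-Seq") and from reduced-representation bisulfite sequencing
    (RRBS C/T tag counts). Provides the historical binary call, a
    closed-form Truncated Proportional Estimate (the maximum-likelihood
    estimator under a Poisson thinning model of HpaII counts), and a
    Bayesian hierarchical Gamma-Poisson model fitted by a native
    Gibbs-within-Metropolis sampler that returns posterior means and
    variances and adjusts for library-wide sequencing-depth bias.
    Includes synthetic-data generators for benchmarking (constant-depth
    Poisson counts, log-normal depth discordance, correlated neighboring
    sites, technical replicates, RRBS), and evaluation statistics
    (correlations, dependent-correlation t-test, Mann-Whitney ROC/AUC,
    replicate consistency, Infinium beta renormalization).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
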