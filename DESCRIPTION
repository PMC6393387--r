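Package: chainpower
Title: Power and Sample Size for Multi-Omics Causal Chain Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic power and minimal sample-size calculations for
    level-specific association tests along the central-dogma causal chain
    (SNP genotype -> RNA expression -> protein expression -> quantitative
    trait) under simple random sampling and extreme phenotype sampling.
    Provides the variance and correlation algebra of the linear causal
    chain (mediate squared correlations, SNP heritability, level-trait
    correlations), truncated-normal tail moments and the fold-change to
    correlation conversion for extreme phenotype designs, noncentral-t
    power and sample-size inversion, the slope and pooled two-sample
    t-tests applied to per-sample data, and a seeded Monte-Carlo simulator
    that validates every analytic quantity. Includes a command-line
    interface for power, sample-size, conversion, testing, simulation and
    reproduction of the package's reference tables and curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
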