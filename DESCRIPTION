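Package: mtxdiff
Title: Differential Expression Models for Paired Metatranscriptomes and
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical models for differential expression (DE) analysis of
    microbial community metatranscriptomes (MTX), optionally paired with
    metagenomes (MGX).  Implements six per-feature regression models that
    differ in how transcript abundances are normalized for underlying gene
    copy number (community total-sum scaling, within-taxon scaling,
    taxon-level RNA or DNA covariates, RNA/DNA ratios and per-feature DNA
    covariates), three zero pre-filtering policies, a logistic
    presence/absence variant, and a synthetic paired MGX/MTX community
    simulator with spiked phenotype associations for benchmarking type-I
    error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
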