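Package: microrecov
Title: Disturbance and Recovery Dynamics of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising microbial community responses to
    disturbance across environments from 16S rRNA amplicon count tables.
    Provides rarefaction and Hill-number diversity, sample-completeness
    (coverage) estimation, Bray-Curtis dispersion and turnover pair sets
    with replicate-aware exclusion rules, a richness-preserving permutation
    null model with Z-scores, hierarchical Bayesian before-after and
    time-series models (negative-binomial, Beta, and heteroskedastic
    Gaussian families) with credible-interval trend classification, a
    multi-study synthetic time-series generator with environment presets,
    and an end-to-end pipeline producing classification summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
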