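Package: thiometa
Title: Meta-Analysis of NUDT15 Variants and Thiopurine Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for pharmacogenetic meta-analysis of the
    NUDT15 missense variant rs116855232 against thiopurine-induced
    myelotoxicity and thiopurine intolerance dose. Builds per-study
    contingency tables under allele, dominant, recessive and genotype
    contrasts; pools odds ratios by Mantel-Haenszel or inverse-variance
    fixed effects and DerSimonian-Laird random effects with Cochran Q,
    I-squared and tau-squared heterogeneity; runs Egger regression and
    Begg rank-correlation publication-bias tests, leave-one-out
    sensitivity analysis and funnel/forest data export; normalizes
    per-genotype dose summaries against the CC reference group and pools
    carrier-versus-CC mean differences; and performs an additive-dosage
    cis-eQTL linear-regression scan. Ships the published study table as
    a plain-text fixture plus seeded generators for simulated cohorts
    and genotype-expression panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
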