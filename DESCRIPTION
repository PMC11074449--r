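Package: tumorlr
Title: Likelihood Ratios for Tumor Tissue Source Identification from STR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Continuous probabilistic genotyping for tumor tissue. Models a
    tumor STR profile as a mixture of a normal cell population and K-1 tumor
    subclones whose genotypes may deviate from the somatic reference through
    STR variants (additional alleles, replacement alleles, partial or
    complete loss of heterozygosity) occurring at a per-locus incidence phi.
    Peak heights follow a gamma model with a log-linear DNA degradation term
    and analytical-threshold dropout. Computes likelihood ratios for the
    hypothesis that the tumor originates from a known individual against
    unrelated or related (parent-offspring, full-sibling) alternative
    sources, with the normal-cell fraction supplied a priori. Includes a
    synthetic-data generator, non-contributor (Hd-true) testing, sensitivity
    grids over the a priori parameters, and gamma/degradation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
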