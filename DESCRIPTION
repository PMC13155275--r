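Package: smokiron
Title: Bidirectional Phenotypic, Genetic and Causal Analysis of Smoking and Striatal Iron
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking an exposure trait (tobacco
    smoking) to quantitative brain-iron phenotypes (T2* and QSM in the
    striatum): de-confounded phenotypic association with rank-based inverse
    normal transformation and FDR control; LD-score regression for
    heritability, genetic covariance, genetic correlation and the
    sample-overlap intercept; gene-level cross-GWAS coherence and directional
    ratio tests with LD-aware weighted chi-square null distributions; and a
    two-sample Mendelian randomisation suite (IVW, MR-Egger, weighted median,
    weighted mode) with the usual sensitivity battery. Ships synthetic-data
    generators for haplotype reference panels with block LD, paired GWAS
    summary statistics with configurable cross-trait architecture and sample
    overlap, and cohort phenotype tables with known effects, so every stage
    is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
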