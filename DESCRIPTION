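Package: divqtl
Title: Multi-Ancestry cis-QTL Mapping, Fine-Mapping and Population
    Differentiation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cis-QTL analysis in structured,
    multi-ancestry cohorts. Partitions expression and splicing variance
    between continental groups and populations with permutation nulls,
    maps cis-eQTLs and cis-sQTLs with permutation-based gene-level FDR
    control, fine-maps independent signals with a sum-of-single-effects
    model yielding 95 percent credible sets, estimates conditional
    allelic-fold-change effect sizes, classifies frequency-differentiated
    QTLs with Hudson F_ST and negative-binomial differential expression,
    tests genotype-by-ancestry effect-size heterogeneity under single-
    and multi-causal models, computes matched-background functional
    enrichment, and evaluates colocalization posteriors. Includes a
    nested Balding-Nichols simulator of structured-population genotypes
    and aFC-generative phenotypes with machine-readable ground truth.
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
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
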