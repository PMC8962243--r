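Package: conjfdr
Title: Cross-Trait Pleiotropy Analysis with Conditional and Conjunctional FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genetic loci shared between two GWAS traits from
    summary statistics alone. Implements conditional quantile-quantile
    enrichment curves with LD-based random pruning, conditional and
    conjunctional false-discovery-rate (condFDR/conjFDR) estimation,
    clumping of significant variants into independent shared loci, plus
    downstream two-sample Mendelian-randomization estimators (Wald ratio,
    inverse-variance weighted, weighted median) and a differential-expression
    stage with Benjamini-Hochberg correction. Ships seeded generators for
    synthetic summary statistics, LD tables, MR instruments and expression
    matrices so every stage can be exercised and calibrated without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    igraph,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
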