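Package: rifnet
Title: Regulatory Impact Factors and Differential Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes "silent" causal regulators -- genes that drive a
    phenotypic contrast without themselves being differentially expressed --
    from two-condition gene expression data. Implements the phenotype impact
    factor (PIF), regulatory impact factors (RIF1, RIF2), differential
    co-expression (dC), co-differential expression (CdE), PCIT
    (partial-correlation-and-information-theory) edge significance testing,
    co-expression and co-differential co-expression network construction,
    significant-degree contrasts, module-driver scoring, and topology and
    abundance diagnostics, together with a seeded synthetic-data generator
    that plants a rewired silent regulator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
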