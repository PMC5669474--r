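Package: chemomics
Title: Chemostat Metabolic Phenotypes and Phenome-Anchored Multi-Omics Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes steady-state metabolic phenotypes of glucose-limited
    chemostat cultures (molar end-product yields, specific production rates,
    production fluxes and carbon balances of mixed-acid fermentation) and
    implements a phenome-anchored feature-selection workflow for paired
    proteome and transcriptome data: RPKM normalization with rRNA exclusion,
    principal component analysis, two-factor ANOVA with rotation-test false
    discovery rate adjustment, repeated multi-response elastic net stability
    selection with cross-validated regularization, fold-change confidence
    interval validation per strain, principal-component pattern grouping and
    phenome correlation reporting. A synthetic-data generator emulates the
    2-strain x 2-growth-rate x 3-replicate study design with planted,
    group-structured effects so that the whole pipeline is testable end to
    end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
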