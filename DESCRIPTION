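Package: kinpred
Title: Polygenic Prediction Exploiting Relatives with PRS, GBLUP and Single-Step HBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how close relatives
    between discovery and target samples affect polygenic prediction accuracy.
    Simulates nuclear-family pedigrees, Mendelian gene-dropped genotypes and
    phenotypes with additive-genetic, shared-family and residual components;
    builds genomic (G), pedigree (A) and combined (H) relationship matrices;
    constructs relatedness-controlled study designs; computes polygenic risk
    scores and BLUP predictions (GBLUP, ABLUP, single-step HBLUP) with REML
    variance components; and compares empirical prediction accuracy against
    the theoretical accuracy implied by the effective number of chromosome
    segments estimated from the variance of discovery-target genomic
    relationships.
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
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
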