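Package: epigblup
Title: Genomic Prediction with Dominance and Epistatic Variance Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimation of additive and non-additive (dominance,
    additive-by-additive, additive-by-dominance and dominance-by-dominance
    epistatic) genetic variance components from SNP data. Builds VanRaden
    additive and Vitezica dominance genomic relationship matrices and their
    trace-normalised Hadamard-product epistatic counterparts, fits
    multi-component mixed models by average-information REML with an
    expectation-maximisation fallback, supports repeatability models with
    permanent environmental effects and inbreeding-depression covariates,
    and assesses predictive ability of genomic breeding values with the
    Linear Regression (LR) cross-validation method (bias, dispersion,
    accuracy). Includes a pedigree/genotype/phenotype simulator with known
    ground truth, genotype quality control, and model-comparison tools
    (AIC, likelihood-ratio tests, Spearman re-ranking, top-fraction
    selected-animal overlap).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
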