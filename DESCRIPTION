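Package: enviromics
Title: Envirotyping Pipelines and Enviromic Kernels for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn daily weather records into ecophysiological
    covariates (photoperiod, radiation, thermal time, radiation-use
    efficiency, vapour pressure deficit, Priestley-Taylor
    evapotranspiration), to characterize growing environments by envirotype
    frequencies and environment-by-covariate matrices, to build linear and
    Gaussian enviromic similarity kernels, and to fit Bayesian
    genomic-by-enviromic reaction-norm models for multi-environment trial
    prediction with an eigendecomposition Gibbs sampler. Includes a
    synthetic-data generator for weather, marker-derived kinships and
    multi-environment phenotypes with known variance components, and
    cross-validation schemes for novel genotypes (CV1) and novel
    genotypes in novel environments (CV00).
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
    generics,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
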