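Package: cosmor
Title: Quantitative Modeling of an Obligate Cross-Feeding Yeast Community
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and parameter-estimation tools for a synthetic
    obligate mutualism (CoSMO) between two auxotrophic yeast strains that
    cross-feed lysine and hypoxanthine. Provides the well-mixed community
    ODE model with Moser birth kinetics, single-strain chemostat models and
    the phenotype estimators derived from them (consumption per birth,
    death rate, metabolite release rate, live- versus dead-release
    discrimination), a closed-form steady-state community growth-rate
    prediction with variance-formula error propagation, two-genotype
    mutant-accumulation and chemostat-competition models, a reduced-scale
    reaction-diffusion simulator of community growth on agarose, and a
    synthetic-data generator with multiplicative flow-cytometry-like
    measurement noise for end-to-end validation of the estimators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
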