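Package: mesotox
Title: Chronic Diquat Effects on Non-Target Biota in Outdoor Mesocosms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of a replicated outdoor mesocosm experiment
    on the aquatic herbicide diquat: a Bayesian hormetic (quadratic-logit)
    binomial survival model for caged amphipods with tank-level random
    effects and closed-form derived toxicity metrics (LCx, peak and limiting
    concentrations of stimulation), exact leave-one-out cross-validation for
    model comparison, mixed-model analyses of tadpole endpoints (survival,
    development rate, mass, hepatosomatic index, sex ratio), phytoplankton
    community analytics (Shannon diversity contrasts, Bray-Curtis NMDS,
    PERMANOVA, dispersion homogeneity), exposure-fate summaries with
    detection-limit censoring, and a synthetic mesocosm experiment generator
    that reproduces the statistical structure of every endpoint so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    coda,
    lme4,
    vegan,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    boot,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
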