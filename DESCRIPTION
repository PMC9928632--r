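Package: canpros
Title: Pedigree-Based Prostate Cancer Risk Modelling and Prospective Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Complex segregation analysis and absolute risk prediction for
    prostate cancer. Implements an Elston-Stewart pedigree likelihood over a
    joint genotype space of rare pathogenic variants (BRCA2, BRCA1, HOXB13
    G84E), a hypothetical recessive major gene, and a discretized age-dependent
    polygenic component partially measured by a polygenic score. Genotype-
    specific hazards are constrained so that the population-average incidence
    matches external population incidence tables. Provides maximum-likelihood
    parameter estimation with ascertainment adjustment by conditioning, AIC and
    likelihood-ratio model comparison, posterior genotype inference and
    absolute risk curves for consultands, model-implied familial relative
    risks, prospective validation (fixed-horizon concordance, Kaplan-Meier
    calibration, recalibration, risk classification), and a synthetic-data
    generator for families and cohorts under the full generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
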