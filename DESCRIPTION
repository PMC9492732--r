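Package: leafscale
Title: Leaf Water Content and Temperature Corrections for Leaf Trait Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how leaf water content (LWC) and temperature
    shape bivariate leaf trait scaling relationships. Implements a metabolic
    model in which mass-specific photosynthesis and specific leaf area depend
    on dry-mass-based LWC through a Michaelis-Menten saturation term and on
    temperature through a Boltzmann-Arrhenius factor; provides standardized
    major axis (SMA) regression with analytic confidence intervals and slope
    tests, separable non-linear least-squares fitting of the saturation model
    with non-parametric bootstrap uncertainty and AIC model comparison,
    harmonization of heterogeneous leaf-trait records (derived LWC, unit
    conversions, species-site means, growing-season temperature, latitudinal
    zones), a synthetic trait-data generator for validation, and a pipeline
    that corrects whole-leaf traits and compares scaling exponents across
    plant growth forms, ecosystem types and latitudinal zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
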