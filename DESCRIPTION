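Package: pubertome
Title: Gut-Microbiota Maturation and Pubertal Timing Analysis
Version: 0.1.0
Authors@R: person("Flora", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking gut-microbiota composition to
    pubertal timing in adolescents. Derives pubertal timing (growth take-off
    and age at peak height velocity) from longitudinal height records against
    sex-specific reference velocity curves, computes an adult-similarity
    microbiota maturity index from species-level relative abundances,
    performs Bray-Curtis principal-coordinates ordination with stage-group
    contrasts, runs a diagnostics-driven per-taxon count-regression cascade
    (negative binomial, Poisson, linear, generalized least squares) with
    library-size offsets, and screens antibiotic-exposure summaries and
    multivariate pubertal-timing models by AIC. Includes a fully
    ground-truthed synthetic cohort generator (parametric growth spurts,
    Dirichlet-multinomial communities with a sex-specific maturation
    gradient, exposure metadata) for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    nlme,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    withr
Config/testthat/edition: 3
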