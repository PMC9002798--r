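Package: thermostates
Title: Bayesian Assignment of Metabolic Rate Measurements to Torpor,
    Euthermy and Thermoneutral Rest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns resting metabolic rate measurements taken at varying
    ambient temperature to one of three physiological states - torpor,
    euthermic rest below the thermoneutral zone, or rest within the
    thermoneutral zone - with a three-step Bayesian mixture model built on
    the extended Scholander-Irving model of endotherm thermoregulation.
    Jointly estimates the thermoregulatory curve parameters (lower critical
    temperature, minimal torpid metabolic rate, extrapolated body
    temperatures, torpid rate at the lower critical temperature), reports
    per-measurement assignment confidence with a binomial validity test,
    and diagnoses parameter identifiability through prior-posterior
    overlap. Includes a synthetic-data generator for respirometry-like
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    lmtest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
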