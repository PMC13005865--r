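Package: hepaflux
Title: Postprandial Hepatic and Systemic Glucose Flux Modelling from Oral
    Tracer and Liver Spectroscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of postprandial glucose metabolism from a
    single oral stable-isotope tracer together with hepatic magnetic
    resonance readouts. Implements the single-tracer oral minimal model
    with a gastrointestinal absorption sub-model (meal rate of appearance,
    gastric retention, endogenous glucose production and glucose disposal),
    a two-compartment subcutaneous insulin absorption model with composite
    active-insulin superposition of long-acting analogues, tracer-to-tracee
    partition of plasma glucose into exogenous and endogenous sources,
    water-referenced deuterium metabolic imaging and phantom-referenced
    natural-abundance 13C spectroscopy quantification, cohort summary
    statistics and hierarchical subgroup clustering, and a mechanistic
    synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
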