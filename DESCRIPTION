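Package: rxrisk
Title: Medication-Based Rx-Risk Comorbidity Index and Registry Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building the medication-based Rx-Risk Comorbidity Index
    from prescription-registry dispensing records: mapping ATC codes to disease
    categories, calibrating calendar-year severity weights from one-year
    mortality, and scoring individuals per calendar year. On top of the index
    the package constructs an open hip-fracture cohort with the lagged score as
    a time-varying exposure, computes standardized incidence rates, and fits
    negative-binomial incidence-rate-ratio models (banded, continuous,
    stratified, latency and sensitivity variants). A seeded synthetic registry
    generator produces linked person, dispensing and fracture tables so that
    every stage is testable by parameter recovery without access to restricted
    national registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
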