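Package: beatr
Title: Zone-Based Biosecurity Assessment and Health-Plan Evaluation for Broiler Farms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a zone-based biosecurity assessment tool (BEAT) for
    broiler farms: a questionnaire scoring engine over the five-zone farm
    model (green broiler house through red external areas) with relative
    compliance scores and traffic-light classification; tailor-made health
    plan (intervention) accounting by zone, cost and time horizon;
    per-cycle flock monitoring of antimicrobial use, footpad lesions and
    mortality; the pre/post-intervention statistical evaluation (rank
    tests, linear mixed model for footpad scores with AIC forward
    selection); and a synthetic multi-country cohort generator so the
    whole pipeline is testable without farm-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
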