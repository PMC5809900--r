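Package: vfscreen
Title: Markov Cohort Model for Vertebral Fracture Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic Markov cohort model comparing population screening
    strategies for prevalent vertebral fractures (spine radiography following
    vertebral fracture assessment, vertebral fracture assessment alone, and
    spine radiography alone) against no screening, over a 10-year horizon in
    adults aged 50 and older. Computes cumulative new vertebral fracture
    incidence, discounted per-capita cost, and cumulative radiation exposure
    for each strategy, together with incremental outcomes versus no screening,
    univariate and scenario sensitivity analyses, an individual-level
    microsimulation used as a Monte-Carlo cross-check of the cohort engine,
    and an exhaustive search over under-determined modelling conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
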