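Package: sodiumcra
Title: Comparative Risk Assessment of Sodium Reformulation Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the deaths, incident cases and disability-adjusted
    life years (DALYs) from cardiovascular disease, chronic kidney disease
    and stomach cancer that could be averted if packaged foods complied
    with maximum sodium content targets. Implements a four-stage
    comparative risk assessment: survey-weighted sodium intake estimation
    from 24-hour diet recalls with urinary-excretion underreporting
    adjustment; sales-weighted reformulation modelling at product level;
    potential impact fractions with blood-pressure-mediated and direct
    relative-risk pathways; and Monte Carlo propagation of input
    uncertainty with percentile summaries. Includes a synthetic data
    generator emulating the required survey, food-supply and disease
    burden inputs, per-category and per-company attribution, scenario
    comparison, and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
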