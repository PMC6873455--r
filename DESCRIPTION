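Package: bundlevar
Title: Regional Variation in Bundled Surgical Episode Payments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 90-day surgical episodes of care from insurance claims,
    allocates payments into index hospitalization, readmission, post-acute
    care and professional-fee components, price-standardizes payments with a
    wage-index deflator, fits a log-link case-mix model with a multiplicative
    gamma random effect per hospital referral region (HRR), produces
    empirical-Bayes reliability-adjusted mean costs per HRR, and reports
    inter-quintile variation per procedure and payment component. Includes a
    synthetic claims generator with known ground truth so the full pipeline
    is testable without restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
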