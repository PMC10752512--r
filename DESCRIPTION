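Package: youthadrev
Title: Simulated Age-Specific Social Media Advertising Revenue Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates, by single year of age, the number of U.S. users of
    social media platforms and the annual advertising revenue attributable
    to youth (ages 0-12 and 13-17). Survey prevalence and minutes-per-day
    estimates reported by age group are sampled with their margins of error,
    disaggregated to single-year-of-age profiles with natural cubic splines,
    calibrated to external platform user totals by a seeded stochastic
    search, and revenue is allocated in proportion to person-minutes under a
    constant revenue-per-minute assumption. Uncertainty intervals come from
    the ensemble of best-fitting parameter sets. A synthetic-data generator
    with known ground truth replaces the proprietary market-research inputs
    so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
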