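Package: shortageimpact
Title: Patient-Impact Scoring of Medicine Shortages with an ECHO-Based Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rates medicine shortages on the five elements that drive their
    impact on patients (alternative product, disease, susceptibility, costs,
    number of patients affected) on an ordinal low/moderate/high scale,
    multiplies the element scores into an overall impact score (1-243), and
    rolls the elements up to economic, clinical and humanistic (ECHO)
    outcomes. Includes shortage-registry I/O with episode merging and
    eligibility filtering, cohort-level summaries (characterisation tables,
    finite-population sample-size calculation, chi-square representativeness
    tests, Kruskal-Wallis and Dunn comparisons of stratified scores, rating
    distributions and yearly trends), and a seeded synthetic-cohort generator
    that emulates the marginal structure of the Dutch 2012-2015 shortage
    cohort so the whole pipeline runs without confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
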