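Package: benchtopsis
Title: Benchmark-Anchored TOPSIS with AHP Weights for City Health-Sustainability Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Scores a single city against published health-indicator
    standards (HIS) instead of against other cities.  Indicator weights
    are derived from Saaty pairwise-comparison matrices by the
    column-normalize/row-average method and gated by the consistency
    ratio; the city is then placed in a three-row TOPSIS decision matrix
    together with the positive- and negative-ideal benchmark rows, and
    relative closeness is aggregated per indicator, element, and
    dimension.  Ships the 45-indicator, 15-element, four-dimension
    health-sustainability framework with its Khon Kaen 2019 worked
    example, a three-level improvement-strategy classifier, an IOC
    expert-screening helper, and a seeded synthetic generator for
    frameworks, near-consistent judgment matrices, and city observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
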