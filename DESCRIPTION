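Package: foodriskindex
Title: Small-Area Household Food Insecurity Risk Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs and validates composite small-area indices of
    household food insecurity risk for English LSOA-like geographies.
    Implements rank-based inverse normal (Rankit) indicator scoring,
    equal-weight domain scores, the IMD-style exponential domain
    transformation, composite ranking with competition (minimum-rank)
    ties and decile assignment, LSOA-to-MSOA aggregation, and an
    agreement-based validation battery (Spearman rank correlation,
    decile chi-square, two-way mixed-effects intraclass correlation
    with confidence intervals, urban/rural stratification, regional
    top-decile summaries). A seeded synthetic small-area generator
    emulates the latent-factor structure of the real inputs so the
    whole pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
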