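Package: paesignal
Title: Pandemic-Associated Adverse Event Signal Detection from Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse drug events whose reporting pattern changed with the
    onset of a nationwide public-health emergency, from FAERS-style spontaneous
    report data. Implements a three-stage screen: disproportionality estimation of
    each adverse event against the pandemic period (reporting odds ratio with Wald
    confidence interval, two-tailed Fisher exact test, Bonferroni correction);
    an AR(2) trajectory-deviation index (PAEAI) that removes events whose change
    is explained by their historical reporting trend; and drug-interference
    filtering via cosine-similarity nearest-neighbour propensity matching with
    drug-event (gamma) and pair-pandemic (delta) odds-ratio tests. Includes
    demographic stratification utilities (gender gaps, bootstrap proportions,
    per-million normalisation, system-organ-class rollups, association-network
    export), readers for a simple tab-separated report dialect and FAERS quarterly
    ASCII tables, and a synthetic report generator with planted ground-truth
    signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
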