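Package: netcontrib
Title: Network Knockout Stability Scoring and Compound Combination Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology discovery of minimal active
    compound combinations from multi-herb formulas. Builds a typed
    herb-compound-target network from compound catalogs screened on oral
    bioavailability and drug-likeness, target maps and scored
    protein-protein interaction edges; filters a two-group expression
    matrix into differentially expressed genes and intersects disease,
    syndrome and formula target sets; extracts a core network by
    topological parameters; simulates compound and combination knockouts;
    summarises each surviving network by four stability indicators
    (network centralization, characteristic path length, network
    heterogeneity, robustness); and ranks all compound combinations by an
    entropy-weighted contribution score. Includes a synthetic-data
    generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
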