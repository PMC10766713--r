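Package: mycopanel
Title: Culture-Media Panel Evaluation for Yeast Biodiversity in Water
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating panels of culture media used to recover
    yeast biodiversity from membrane-filtered water samples. Builds
    taxon-by-medium incidence matrices from isolate tables, exhaustively
    scores every media subset against the full panel (species and isolate
    coverage), summarises and ranks panels, and selects minimal panels by
    set cover. Compares panel-size groups with one-way ANOVA and
    Tukey-Kramer multiple comparisons built on a from-scratch studentized
    range distribution. Models the laboratory identification cascade
    (repeated MALDI-TOF MS protocols followed by ITS and D1/D2 barcode
    sequencing) with configurable score and percent-identity thresholds,
    and accounts for reference-database coverage and supplementation gains.
    Quantifies filamentous overgrowth of membranes by logistic invasion
    curves and usable incubation windows. A seeded synthetic community and
    sampling-campaign generator with skewed rank-abundance, medium-specific
    detection and overgrowth censoring makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
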