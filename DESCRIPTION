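Package: raptorcount
Title: Processing Pipeline for Two-Station Raptor Migration Counts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to turn raw visible-migration count records from a
    two-station raptor survey into analysis-ready daily and annual species
    totals. Implements protocol-integrity validation with taxonomic
    degradation of under-specified records, rule-based removal of birds
    double-counted by both stations, hierarchical proportional allocation
    of birds identified only to morphological groups, standardized
    aggregation (annual totals, passage-date quantiles, season windows,
    age structure, early-morning contribution), and a synthetic two-station
    count simulator with per-flock ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
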