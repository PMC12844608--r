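Package: intercrop
Title: Biological Efficiency and Competition Indices for Two-Component
    Intercropping Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replacement-series intercropping trials with
    two component crops (e.g. a grass-legume winter catch crop mixture grown
    against its pure stands). Reads plot-level yield records from randomized
    complete block trials, assembles per-unit pure-stand/mixture performance
    pairs on a dry-matter or nitrogen-uptake basis, and computes the full
    suite of biological efficiency and competition indices: relative yield
    total (land equivalent ratio), land equivalent coefficient, system
    productivity index, area-time equivalent ratio, percentage yield
    difference, land-use efficiency, competitive ratio, aggressivity,
    relative crowding coefficient, actual yield loss, percentage of land
    saved, and the competitive balance index. Includes rank correlations
    between the two crops' per-unit parameters with exact permutation
    p-values at small sample sizes, interpretation rules for each index,
    and a synthetic trial generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
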