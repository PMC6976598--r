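Package: woundscore
Title: Migration and Death Scoring for Wound-Healing (Scratch) Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes drug-induced wound-closure delay in live-imaged
    scratch assays into quantitative cell-migration and cell-death scores.
    Reads plate-format exports of relative wound density and caspase-3/7
    time series, computes control-normalized closure and death changes over
    configurable analysis windows (fixed endpoint, control slope-decline, or
    per-condition half-closure time), fits the death-closure dose landscape
    with a first-order saturation model (linear fallback), apportions the
    closure delay by the tangent angle, derives phenotypic-bias metrics, and
    tests scoring robustness across seeding densities with two-sample
    Kolmogorov-Smirnov comparisons. Includes a mechanistic synthetic-assay
    simulator with known migrastatic and cytotoxic ground truth, plus a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
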