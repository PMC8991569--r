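Package: fermopt
Title: Two-Stage Statistical Optimization of Fermentation Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Plackett-Burman screening and Box-Behnken response-surface
    optimization of culture media, as used to maximize melanin yield in
    submerged fermentation. Builds and validates two-level screening and
    three-level response-surface designs, estimates per-factor main effects
    and pooled t-statistics, fits the full second-order polynomial by least
    squares on coded variables, finds the exact global maximum of the fitted
    quadratic over the coded design cube by face enumeration, and exports
    response-surface grids. Ships the Hortaea werneckii AS1 melanin
    case-study design tables as fixtures and a synthetic-data generator with
    known ground truth so every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
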