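Package: fitproxy
Title: Short-Term Fitness Proxies Validated Against Pedigree Reproductive Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compare short-term fitness proxies (stage-specific
    lifetime reproductive success, individual growth rate, and de-lifed
    fitness) against long-term fitness measured as pedigree-derived
    reproductive values. Implements Monte-Carlo gene dropping through a
    validated pedigree to estimate per-founder reproductive values, allele
    survival probabilities and lineage longevity; stage-structured fitness
    metrics including the individual transition-matrix growth rate and the
    de-lifing estimator of individual contribution to population growth; a
    statistical comparison layer (Fisher-z correlation intervals, dependent
    correlation tests, logistic regression of lineage survival); and an
    individual-based simulator of an isolated passerine population with
    overlapping generations, stage-structured offspring mortality, density
    regulation and a census bottleneck, so that the whole pipeline is
    testable end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
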