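Package: nullassembly
Title: Null-Model Inference for Insular Community Assembly
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing competitive niche partitioning against
    null expectations in island species assemblages: exact probabilistic
    pairwise species co-occurrence analysis of presence-absence matrices
    with positive/negative/random classification and standardized effect
    sizes, guild co-occurrence and geographic-vs-guild cross
    classification, maximum-likelihood fitting and AIC ranking of species
    abundance distribution models (Pareto, broken stick, lognormal and a
    registry of further models), a body-size V-ratio randomization null
    model with source-pool construction, power-law species-area
    regression, and seeded generators of synthetic metacommunities with
    the statistical structure each stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
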