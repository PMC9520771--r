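Package: dcsp
Title: Discovery of Druggable Cancer-Specific Pathways from Pharmacogenomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a drug- and driver-aware pathway activation score (PAS)
    that weights the summed expression of the pathway genes upstream of a
    drug's targets by network-enrichment connectivity between driver genes,
    drug targets and the pathway; a two-statistic screen (robust t versus the
    remaining cancers plus a chi-squared homogeneity statistic) that flags
    pathways activated in exactly one cancer; and downstream validation
    statistics: rank-based normal-score Pearson correlation between PAS and
    drug-response AUC, rediscovery-rate curves, and a label-permutation
    specificity test. A synthetic cohort simulator with planted
    pathway-activation signals makes every stage testable without external
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
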