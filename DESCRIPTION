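Package: prostamine
Title: Mining Subtype-Specific Co-Alterations Associated with Aggressive
    Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies, filters and rank-scores co-alterations that are
    specific to a user-selected prostate-cancer molecular subtype (a gene plus
    a Loss or Gain direction) and associated with metastatic enrichment and
    biochemical relapse. Works on harmonized multi-cohort inputs: discretized
    GISTIC-style copy-number calls, deleterious-mutation flags, expression
    z-scores and clinical endpoints. Also provides the supporting
    alteration-landscape analyses (per-gene directional frequencies, the
    tumor-coverage curve, contiguous alteration hotspots), consensus
    clustering of binary alteration profiles with CDF-area based selection of
    the cluster number, pairwise mutual-exclusivity testing, and a synthetic
    multi-cohort generator with planted co-alteration, expression and survival
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    survival,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
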