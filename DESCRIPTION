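Package: episcape
Title: Landscape Epigenetics of River Networks: MS-AFLP Scoring,
    Differentiation Statistics and Distance-Matrix Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing population epigenetic and genetic structure
    across a riverscape. Converts dual-enzyme (HpaII/MspI) methylation-sensitive
    AFLP fragment profiles into a four-state methylation matrix with the usual
    peak-height, fragment-size and uninformative-locus filters; computes
    per-population state and allele frequencies for epiloci, microsatellites
    and pooled-sequencing SNPs; estimates pairwise standardized differentiation
    (Gst'') on a common engine for all three marker systems; runs two-level
    distance-based AMOVA with permutation tests; reduces site environmental
    variables by PCA into per-axis distance matrices; and performs simple
    Mantel tests and multiple regression on distance matrices (MRM) to
    separate genetic from environmental determinants of epigenetic
    differentiation. A synthetic riverscape generator with tunable
    genetic-epigenetic and environment-marker couplings makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
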