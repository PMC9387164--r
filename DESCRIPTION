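Package: wcnp
Title: Weight-Coefficient Network Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for weight-coefficient network pharmacology of
    multi-component preparations such as essential oils. Computes Kovats
    retention indices of GC-MS components against an n-alkane ladder, derives
    per-component weights from oral bioavailability and relative content
    (A = OB x I), aggregates them to per-target (B) and per-pathway (C)
    weight coefficients, selects differentially expressed genes by FDR and
    fold-change thresholds, intersects component targets with disease genes
    and DEGs to obtain key targets, performs hypergeometric
    over-representation analysis with Benjamini-Hochberg correction, and
    re-ranks enriched pathways by their weight coefficients. Includes
    STRING-style PPI edge filtering, tripartite component-target-pathway
    network construction with SIF/GraphML export, a seeded synthetic-data
    generator with planted signal for end-to-end validation, and a
    one-command pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
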