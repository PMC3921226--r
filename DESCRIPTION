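Package: ignoromics
Title: Defining Tissue Ignoromes from Expression Selectivity and
    Literature Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies genes with intense and selective expression (ISE)
    in a target tissue from multi-platform expression panels, estimates
    each gene's domain-restricted literature with a disambiguation-aware
    query engine, and combines selectivity and literature fractional
    ranks into a harmonic-mean ignorome score that flags functionally
    neglected genes.  Includes time-series analysis of ignorome
    shrinkage, comparative statistics (coexpression connectivity,
    homolog/paralog/domain correlations, hypergeometric GO enrichment),
    reverse complex trait analysis on recombinant-inbred-like strain
    panels (marker LRS mapping, cis-eQTL filters, phenome scans), and a
    seeded synthetic-data generator that emulates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
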