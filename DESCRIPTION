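Package: rvburden
Title: Rare-Variant Gene-Set Burden Analysis for Small Case-Control Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control rare-variant analysis for small exome cohorts:
    maximum-allele-frequency filtering with missing-frequency pass-through,
    zygosity-stratified per-individual burden counts over curated gene groups
    (including the solute carrier superfamily and a neurotransmitter-related
    restricted list), Welch unequal-variance tests of arm differences,
    detection of variants shared by cases and absent in controls,
    hypergeometric over-representation with Benjamini-Hochberg correction,
    and a seeded synthetic cohort generator so the whole pipeline is testable
    without access to protected human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
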