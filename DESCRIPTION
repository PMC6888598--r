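Package: apobec3edit
Title: Detection and Cohort Scoring of APOBEC3-Mediated C-to-U RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects APOBEC3-mediated C-to-U RNA editing from paired RNA and
    DNA (exome) sequencing evidence at a catalog of known editing sites.
    Converts samtools mpileup text or pre-tabulated strand-split base counts
    into reference/variant counts, applies a multi-gate decision tree
    (coverage, germline-polymorphism, one-sided Boschloo unconditional exact
    test of RNA versus DNA variant excess, relative RNA/DNA variant-fraction
    and strand-bias filters) to call per-site per-sample editing levels,
    summarises cohorts into per-sample editing scores and per-site prevalence
    tables, and compares editing-high versus editing-low samples on
    annotations, gene expression and survival. Includes a synthetic paired
    RNA/DNA cohort generator with known ground truth for validating the
    caller's operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
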