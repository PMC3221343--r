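Package: evicite
Title: Evidence-Type Profiling of Citations in Point-of-Care Clinical References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bibliometric evidence profiling of the reference lists
    behind point-of-care (POC) clinical information products. Reads citation
    corpora in MEDLINE/nbib and RIS formats, classifies each citation into a
    nine-category publication-type scheme guided by the evidence hierarchy
    (guideline, systematic review, randomized controlled trial, narrative
    review, primary research, report, animal study, other, unknown), bins
    citations by publication-year currency, and measures cross-product
    citation overlap with both exact (PMID and content-key) and optional
    fuzzy title matching. A deterministic synthetic-corpus generator with
    controlled category composition, year mix, and overlap multiplicity
    makes every pipeline stage testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
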