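Package: dwclens
Title: Reversible Curation of Darwin Core Occurrence Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A community-integrated biodiversity curation pipeline for
    heterogeneous species-occurrence catalogues. Source catalogues are mapped
    onto a Darwin Core core field set, corrected through reversible
    taxon-resolution ("swap") and georeferencing patch files, filtered to a
    project area polygon, summarised per taxon, split into per-phylum expert
    sheets, and iterated to a fixed point in which expert edits raise no
    further discrepancies. A contribution-analysis stage computes per-source
    record and taxon tallies, exclusive versus shared taxon reports, grouped
    novelty percentages and record-to-novel-report ratios. A synthetic
    fixture generator emulates multi-source catalogues with controlled taxon
    overlap, injected name and coordinate errors, and recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
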