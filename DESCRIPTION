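Package: adrkb
Title: Standardized Integration of Drug-Adverse Event Evidence Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a pharmacovigilance evidence base by normalizing heterogeneous
    drug-adverse event evidence sources (product-label NLP output, EU SPC extractions,
    MEDLINE MeSH co-indexing, Semantic MEDLINE sentence spans, spontaneous-report
    counts with proportional reporting ratios, and chemical-disease association
    records) to RxNorm drugs and SNOMED-CT health outcomes via an OMOP-style standard
    vocabulary. Every evidence item is represented as an Open Annotation resource with
    dual graph (Turtle/N-Triples) and relational form; aggregated statistics feed a
    summary store with four rollup granularities, each summary record carrying an
    encoded linkout that resolves back to the exact annotation set behind it. Includes
    seeded fixture generators, coverage/overlap reporting, negative-control search,
    and a temporal join of the evidence base against OMOP CDM-shaped patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
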