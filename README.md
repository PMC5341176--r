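# adrkb — standardized integration of drug–adverse event evidence

Safety physicians and risk-management analysts triaging a potential drug
safety signal need one question answered quickly: *what evidence already
exists that this drug is associated with this health outcome of interest
(HOI)?* The evidence is scattered across product labels, the indexed
literature, curated chemical–disease databases, and spontaneous-report
systems, each coded in a different terminology (RxNorm, MedDRA, MeSH, UMLS
CUIs, free-text drug names).

`adrkb` builds a miniature, fully reproducible evidence base from such
sources:

- **Vocabulary normalization.** An OMOP-style standard vocabulary store maps
  every native drug code to RxNorm and every native HOI code to SNOMED-CT via
  `MAPS_TO` relationships, with ancestor-based traversal from clinical drugs
  (ingredient + strength + form) up to their ingredients, and exact
  normalized-name matching for name-only sources.
- **Open Annotation evidence items.** Every accepted source record becomes an
  annotation with a *target* (the source document, with an exact-text or
  label-section selector) and one or more *bodies* (the standardized drug,
  ingredient, and HOI concepts plus an evidence-type tag). Each annotation
  exists in dual form: rows in `adr_annotation` / `target` / `adr_body`, and
  a blank-node-free RDF graph serializable as Turtle or N-Triples — the two
  are interconvertible and set-equal as triples.
- **Summary store and rollups.** Per-source aggregates (record counts, case
  counts, proportional reporting ratios) live in `drug_hoi_evidence`, keyed
  by `drug_hoi_relationship`. The `laertes_summary` table carries four rollup
  granularities: (1) ingredient, (2) ingredient + HOI, (3) ingredient +
  clinical drug, (4) full detail. Counts aggregate by sum; PRR, being a
  ratio, is carried only at full detail.
- **Linkouts.** Every evidence record stores a canonical
  `laertes://evidence?...` URL plus a base62 short key that resolves to
  exactly the annotation set it aggregates — the bridge from a summary row to
  its drill-down evidence.
- **Clinical-data join.** `count_exposed_cases()` joins the evidence base
  against CDM-shaped `drug_era` / `condition_era` tables, counting distinct
  patients whose condition era starts within 30 days (strictly after) a drug
  era start, restricted to chosen evidence types.
- **Negative controls.** `find_negative_controls()` returns candidate
  drug–HOI pairs with zero evidence in any loaded source, the raw material
  for calibrating observational effect estimates.

Seeded fixture generators (`generate_vocabulary()`, `generate_source()`,
`generate_cdm()`) produce all input shapes deterministically with a
ground-truth manifest, so every pipeline property is testable end to end.

## Worked example

```r
library(adrkb)
d <- tempfile()
suite <- generate_fixture_suite(d, seed = 7, n_records = 12)
store <- evidence_store()
run_etl("MEDLINE_MESH", suite$sources$MEDLINE_MESH$path, suite$vocab, store)
#> <etl_report> MEDLINE_MESH: 12 read, 12 normalized, pairs 12/12 (100.0%), 0 reject(s)
run_etl("FAERS", suite$sources$FAERS$path, suite$vocab, store)
store
#> <evidence_store> 24 annotations, 36 evidence records, 0 summary rows

s <- build_rollups(store, suite$vocab)
head(s[s$rollup_level == 2, ], 3)
#>    rollup_level ingredient_concept_id clinical_drug_concept_id hoi_concept_id
#> 16            2               1539403                       NA       46000001
#> 17            2               1539403                       NA       46000001
#> 18            2               1539403                       NA       46000002
#>      evidence_type statistic_type aggregate_value
#> 16 FAERS_CaseCount     CASE_COUNT               7
#> 17 MEDLINE_MeSH_CR   RECORD_COUNT               1
#> 18 MEDLINE_MeSH_CR   RECORD_COUNT               1
```

Level-2 rows aggregate per (ingredient, HOI): ingredient 1539403
(simvastatin) has one MEDLINE case report and 7 spontaneous-report cases for
HOI 46000001. Each evidence record's linkout drills down to the exact
annotations behind it:

```r
ev <- store$drug_hoi_evidence[1, ]
ev$evidence_linkout
#> laertes://evidence?atype=ohdsi%3APubMedDrugHOIAnnotation&drug=1539403&hoi=46000001&source=MEDLINE_MESH&type=MEDLINE_MeSH_CR
linkout_resolve(store, ev$evidence_linkout)[[1]]
#> <oa_annotation #7> ohdsi:PubMedDrugHOIAnnotation, 1 body(ies), target http://www.ncbi.nlm.nih.gov/pubmed/20000007
```

The same pipeline is scriptable from a shell via the thin CLI at
`inst/cli/adrkb` (subcommands `gen-fixtures`, `load-vocab`, `etl`,
`summarize`, `rollup`, `coverage`, `overlap`, `negative-controls`, `query`,
`resolve`, `cdm-join`).

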