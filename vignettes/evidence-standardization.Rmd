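---
title: "Standardizing and aggregating drug–adverse event evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing and aggregating drug–adverse event evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrkb)
```

## The problem and the model

Pharmacovigilance evidence for a drug–HOI (health outcome of interest)
association is spread over sources that disagree on coding: US product-label
NLP output codes drugs in RxNorm at the *clinical drug* level and outcomes in
MedDRA; EU SPC extractions name drugs as free text; MEDLINE co-indexing and
chemical–disease databases use MeSH for both sides; Semantic MEDLINE uses
UMLS CUIs; spontaneous-report summaries carry RxNorm codes with case counts
and a proportional reporting ratio (PRR). `adrkb` normalizes all of them to
one drug terminology (RxNorm) and one condition terminology (SNOMED-CT)
through an OMOP-style standard vocabulary, then represents, aggregates, and
cross-links the evidence.

The pipeline has three stages per source, mirroring a classic ETL pattern:

1. **Transform** — each raw record is resolved to standard (drug, HOI) pairs
   by the source's terminology route. Mapping fan-out is preserved: a native
   code with several `MAPS_TO` targets produces one pair per target, because
   collapsing many-to-many mappings would silently discard evidence. Records
   whose drug or HOI cannot be resolved are *rejections* with a reason
   (`DRUG_UNMAPPED`, `HOI_UNMAPPED`, `BOTH_UNMAPPED`); a record that does not
   even match the source's column shape is a parse error and aborts the load,
   since shape violations indicate corruption rather than expected coverage
   loss.
2. **Load** — each accepted record becomes an Open Annotation item: a target
   (source document URI plus a selector — exact text for literature sources,
   label section for label sources, none for count-style sources) and bodies
   holding the standardized concepts and an evidence-type tag. Annotations
   exist simultaneously as relational rows and as a blank-node-free triple
   graph; because every node's URI is minted deterministically from the
   annotation uid, graph/relational equality is a decidable set comparison,
   which the test suite exploits.
3. **Derive** — per-source aggregates are written to the summary store: record
   counts (number of annotations per pair and evidence type), case-count sums,
   and PRR pass-through, each with a linkout.

### Evidence types

The five literature/label tags follow the summary-store naming convention
(`MEDLINE_MeSH_CR`, `MEDLINE_MeSH_ClinTrial`, `MEDLINE_SemMedDB_CR`,
`MEDLINE_SemMedDB_ClinTrial`, `SPL_EU_SPC`). Tags that convention leaves
unnamed are extended consistently: `MEDLINE_*_Other` for uncategorized
publication types, `SPL_SPLICER` for US labels, `CTD_ChemicalDisease`, and
`FAERS_CaseCount` / `FAERS_PRR` for the two spontaneous-report statistics. A
FAERS record yields **one annotation with two bodies** (one per statistic):
that preserves "one annotation per accepted record and pair" while letting
both derived evidence records resolve their linkouts to the same underlying
item.

All shipped adapters emit modality `SUPPORTS`; `REFUTES` is carried in the
schema for completeness but no shipped source defines a refutation rule.

### Rollups

Evidence attaches to drugs at two granularities: clinical drug (only the US
label source) and ingredient (everything else). Before aggregation every
clinical-drug record is attributed to its ingredient(s) via the vocabulary's
ancestor closure; the summary table then holds four granularities —
ingredient; ingredient + HOI; ingredient + clinical drug; full detail.
Two numerical decisions matter here:

- **PRR is never summed.** A reporting ratio is not additive across drugs or
  outcomes, so levels 1–3 omit it and it appears only at full detail. The
  alternative (averaging) would manufacture a statistic no source computed.
- **Level 1 aggregates over all HOIs**, taking the "by ingredient" grouping
  literally. An alternative reading (per-HOI totals per ingredient) is
  exactly level 2, so nothing is lost by implementing level 1 as the coarsest
  marginal.
- Drugs that map to several ingredients contribute to each ingredient's
  rollup, consistent with mapping fan-out; evidence whose drug has no
  ingredient ancestor is routed to a reject report rather than silently
  dropped.

HOI-side hierarchy rollups (aggregating a specific condition into its SNOMED
parent) are deliberately out of scope: unlike the drug hierarchy, conditions
offer no single obviously-correct rollup level. The fixture vocabulary still
plants one SNOMED is-a pair so that future hierarchy code has something to
test against.

### Linkouts

Each evidence record's linkout is a canonical URL
(`laertes://evidence?...`, parameters percent-encoded and sorted) plus a
short key. The shortener is a sequential counter rendered in base62 over
`[0-9A-Za-z]` — not a hash, so collisions are impossible by construction, and
the counter is recovered from the persisted keys on reopen. Minting is
idempotent (same arguments return the same key) and refuses to create a
linkout with zero matching annotations, so every summary row can always be
drilled down. Resolution of the long and short form is identical and returns
exactly the annotation set recorded at mint time.

### Clinical-data join

`count_exposed_cases()` reproduces a temporal cohort count over CDM-shaped
patient data: a person qualifies for a (drug, HOI) pair when a condition era
starts strictly after a drug era start and within the window
(`0 < Δdays ≤ 30` by default, calendar-day difference, timezone-free).
The join is on **exact concept ids** — no ingredient expansion of the
patient-side drug codes — because CDM drug-era tables are already
ingredient-level in practice; callers wanting expansion can pre-map their
CDM. The drug era's end date is carried but not filtered on, matching the
window definition above. Patients are counted distinct per output row.

## The fixture generators

The generators emulate the *shapes and coding systems* of the six source
families, not their content:

- `generate_vocabulary(n_ingredients, drugs_per_ingredient, n_conditions,
  seed)` builds ingredients with clinical drugs (ancestor rows), MeSH drug
  synonyms, and SNOMED conditions with MedDRA and MeSH synonyms, all with
  `MAPS_TO` rows into the standard concepts. Synthetic concept ids are
  partitioned by vocabulary (RxNorm near 1.5–2.1M, MedDRA 35M, MeSH 44M,
  SNOMED 45–46M) so id collisions are structurally impossible. Three planted
  concepts (simvastatin, Simvastatin 20 MG Oral Tablet, Rhabdomyolysis) are
  fixed across seeds so drill-down examples are stable; all other names come
  from the seeded RNG.
- `generate_source(kind, vocab, n_records, unmappable_fraction, seed)` samples
  **distinct** native pairs (so coverage arithmetic is exact) and plants
  exactly `round(n_records × unmappable_fraction)` records whose drug code is
  syntactically valid but unregistered — exercising the mapping-miss path,
  not the parser. The highest-id ingredient and condition are never sampled;
  every pair involving them is a guaranteed negative control, which makes the
  negative-control search testable without cross-source bookkeeping. The
  Semantic MEDLINE generator also emits a two-column CUI→concept crosswalk,
  standing in for a UMLS concordance table so the CUI path is exercised
  without shipping UMLS.
- `generate_cdm()` plants one person per (drug, condition, day-offset) triple
  and fills the population with background persons whose era offsets always
  fall outside `(0, 30]` — so the generated truth table is exact even under a
  brute-force scan of all pairs.

What the generators do **not** emulate: realistic adverse-event incidence or
reporting rates, narrative text (selectors carry opaque strings), duplicate
and near-duplicate source records, partially overlapping vocabulary versions,
or the long-tailed pair-frequency distributions of real databases. Passing
tests therefore demonstrate the pipeline's *correctness properties*
(normalization routes, duality, conservation, round trips, boundaries), not
its coverage performance on real extracts — real-world mapping percentages
depend on terminology quality, which is exactly what synthetic fixtures
cannot reproduce.

## Numerical and interface choices

- **Percentages** (coverage, overlap) are reported at one decimal with
  round-half-even; a zero-denominator percentage renders as an em dash, not
  `0`, because "no pairs" is undefined coverage rather than zero coverage.
- **Name matching** is exact after case-folding, trimming, whitespace
  collapsing, and optional stripping of one trailing salt-form word
  (`sodium`, `hydrochloride`, ...). No fuzzy matching: deterministic behavior
  is worth more here than a few extra matches, and ontology-search fallbacks
  are out of scope.
- **Idempotent reloads.** `run_etl()` replaces a source's previous rows by
  default (rerunning a load must not duplicate evidence); `replace = FALSE`
  turns a duplicate load into an error for pipelines that want strictness.
- **Store persistence** is a directory of sorted TSV tables (one per
  relational table). Annotations are rebuilt from their relational rows on
  open — the rows are a lossless copy — and the linkout counter is recovered
  by decoding the persisted keys, so a reopened store continues the key
  sequence without a separate metadata file. Sorted writes make exports
  byte-comparable, which is how the determinism property is checked.
- **RDF subset.** The Turtle/N-Triples writer and reader cover exactly the
  emitted subset (full-URI subjects/objects, prefixed predicates, plain
  literals with `\" \\ \n \t` escapes). The graph carries the drug, HOI and
  evidence-type of each body; the ingredient attribution and identification
  method live only in the relational copy, keeping the per-annotation triple
  count a fixed function of body and selector counts.

## Problem sizes

The shipped tests and the acceptance script run on fixture suites of 48
records per source over a vocabulary of 8 ingredients × 2 clinical drugs and
10 conditions (≈ 216 annotations across all six kinds), and a 500-person
simulated population with planted day-offsets {0, 1, 30, 31} around the join
boundary. These sizes exercise every code path — fan-out, rejection,
reservation, boundaries — while keeping a full run in seconds.

## Known limitations

- Vocabulary loading validates referential integrity and standard-target
  rules but not valid-date semantics of real OMOP vocabulary downloads.
- The EU SPC route matches exact normalized names only; combination products
  ("drug A / drug B") will not match and are reported as `DRUG_UNMAPPED`.
- The relational store is in-memory; the design targets desk-scale evidence
  bases, not the tens of millions of pairs of production systems.
- `REFUTES` modality and HOI-hierarchy rollups are schema-ready but
  unimplemented, as discussed above.
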