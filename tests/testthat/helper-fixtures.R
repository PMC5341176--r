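# Shared fixture builders: a tiny hand-built vocabulary with deliberate
# fan-out cases, and a cached full pipeline over generated sources.

ALL_KINDS <- c("SPL_US", "EU_SPC", "MEDLINE_MESH", "MEDLINE_SEMMED", "FAERS", "CTD")

# Hand-built vocabulary with known fan-out / missing-hierarchy cases:
#   simvastatin (1539403) -> clinical drugs 1539411 + 1539412
#   warfarin (2000001)
#   MeSH drug 44000009 maps to BOTH ingredients (drug-side fan-out)
#   MeSH condition 44500002 maps to BOTH SNOMED conditions (HOI fan-out)
#   clinical drug 2109999 has no ingredient ancestor
tiny_vocab <- function() {
  concepts <- data.frame(
    concept_id = c(1539403L, 2000001L, 1539411L, 1539412L, 2109999L,
                   45619309L, 46000001L,
                   35000001L, 35000002L,
                   44000001L, 44000009L, 44500001L, 44500002L),
    source_code = c("36567", "11289", "316672", "316673", "999001",
                    "240131006", "129565002",
                    "10039020", "10028641",
                    "D019821", "D999001", "D012206", "D999002"),
    name = c("simvastatin", "warfarin",
             "Simvastatin 20 MG Oral Tablet", "Simvastatin 40 MG Oral Tablet",
             "Orphan 10 MG Oral Tablet",
             "Rhabdomyolysis", "Myopathy",
             "Rhabdomyolysis", "Muscle disorder",
             "Simvastatin", "Statin compound", "Rhabdomyolysis", "Muscular Diseases"),
    vocabulary_id = c("RXNORM", "RXNORM", "RXNORM", "RXNORM", "RXNORM",
                      "SNOMED", "SNOMED", "MEDDRA", "MEDDRA",
                      "MESH", "MESH", "MESH", "MESH"),
    concept_class = c("INGREDIENT", "INGREDIENT", "CLINICAL_DRUG",
                      "CLINICAL_DRUG", "CLINICAL_DRUG",
                      "CONDITION", "CONDITION", "CONDITION", "CONDITION",
                      "OTHER", "OTHER", "OTHER", "OTHER"),
    is_standard = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  mappings <- data.frame(
    source_concept_id = c(35000001L, 35000002L, 35000002L,
                          44000001L, 44000009L, 44000009L, 44500001L,
                          44500002L, 44500002L),
    target_concept_id = c(45619309L, 45619309L, 46000001L,
                          1539403L, 1539403L, 2000001L, 45619309L,
                          45619309L, 46000001L),
    relationship = "MAPS_TO"
  )
  ancestors <- data.frame(
    ancestor_concept_id = c(1539403L, 1539403L),
    descendant_concept_id = c(1539411L, 1539412L)
  )
  vocabulary_store(concepts, mappings, ancestors)
}

# Raw-record constructors in the source shapes.
spl_record <- function(code, meddra, label = "SPL00001",
                       section = "ADVERSE REACTIONS") {
  list(label_id = label, set_id = paste0("set-", label), section_name = section,
       rxnorm_clinical_drug_code = code, meddra_hoi_code = meddra,
       mention_text = "Rhabdomyolysis was reported.")
}
mesh_record <- function(drug, hoi, pub_type = "CASE_REPORT", pmid = "20000001") {
  list(pmid = pmid, mesh_drug_code = drug, mesh_hoi_code = hoi,
       pub_type = pub_type, title_abstract_text = "A drug-event report.")
}
faers_record <- function(drug, hoi, count = 12, prr = 2.4) {
  list(drug_code = drug, hoi_code = hoi, case_count = count, prr = prr)
}

# Run the full six-source pipeline on generated fixtures.
build_pipeline <- function(seed, n_records, unmappable_fraction = 0,
                           dir = tempfile("suite")) {
  suite <- generate_fixture_suite(dir, seed, n_records = n_records,
                                  unmappable_fraction = unmappable_fraction)
  store <- evidence_store()
  reports <- list()
  for (k in ALL_KINDS) {
    reports[[k]] <- run_etl(k, suite$sources[[k]]$path, suite$vocab, store)
  }
  list(suite = suite, vocab = suite$vocab, store = store, reports = reports,
       dir = dir)
}

# One cached pipeline reused by read-only tests (>= 200 annotations, 25%
# unmappable records per source).
.pipeline_cache <- new.env(parent = emptyenv())
shared_pipeline <- function() {
  if (is.null(.pipeline_cache$p)) {
    .pipeline_cache$p <- build_pipeline(seed = 101, n_records = 48,
                                        unmappable_fraction = 0.25)
  }
  .pipeline_cache$p
}
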