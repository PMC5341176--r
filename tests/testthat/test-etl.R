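test_that("evidence_type_for reproduces the summary-store tag vocabulary", {
  expect_equal(evidence_type_for("MEDLINE_MESH", "CASE_REPORT"), "MEDLINE_MeSH_CR")
  expect_equal(evidence_type_for("MEDLINE_MESH", "CLIN_TRIAL"), "MEDLINE_MeSH_ClinTrial")
  expect_equal(evidence_type_for("MEDLINE_SEMMED", "CASE_REPORT"), "MEDLINE_SemMedDB_CR")
  expect_equal(evidence_type_for("MEDLINE_SEMMED", "CLIN_TRIAL"), "MEDLINE_SemMedDB_ClinTrial")
  expect_equal(evidence_type_for("EU_SPC"), "SPL_EU_SPC")
  # extensions of the same naming scheme
  expect_equal(evidence_type_for("MEDLINE_MESH", "OTHER"), "MEDLINE_MeSH_Other")
  expect_equal(evidence_type_for("SPL_US"), "SPL_SPLICER")
  expect_equal(evidence_type_for("CTD"), "CTD_ChemicalDisease")
  expect_equal(evidence_type_for("FAERS", statistic_type = "CASE_COUNT"), "FAERS_CaseCount")
  expect_equal(evidence_type_for("FAERS", statistic_type = "PRR"), "FAERS_PRR")
  # total over the enum, given its required argument
  for (pt in c("CLIN_TRIAL", "CASE_REPORT", "OTHER")) {
    expect_type(evidence_type_for("MEDLINE_MESH", pt), "character")
    expect_type(evidence_type_for("MEDLINE_SEMMED", pt), "character")
  }
  expect_error(evidence_type_for("MEDLINE_MESH"), "pub_type")
})

test_that("normalize_record resolves each kind's terminology route", {
  v <- tiny_vocab()
  # US label: clinical-drug code lookup + single MedDRA->SNOMED map
  res <- normalize_record(spl_record("316672", "10039020"), "SPL_US", v)
  expect_null(res$rejection)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$drug_concept_id, 1539411L)
  expect_equal(res$pairs$ingredient_concept_id, 1539403L)
  expect_equal(res$pairs$hoi_concept_id, 45619309L)
  expect_equal(res$pairs$evidence_type, "SPL_SPLICER")
  expect_equal(res$pairs$modality, "SUPPORTS")

  # EU SPC: unknown drug name -> DRUG_UNMAPPED rejection
  eu <- list(doc_id = "EU1", drug_name = "unobtainium", meddra_hoi_code = "10039020")
  expect_equal(normalize_record(eu, "EU_SPC", v)$rejection, "DRUG_UNMAPPED")

  # MeSH HOI mapping to 2 SNOMED targets -> 2 pairs, identical provenance
  res <- normalize_record(mesh_record("D019821", "D999002"), "MEDLINE_MESH", v)
  expect_equal(nrow(res$pairs), 2)
  expect_equal(sort(res$pairs$hoi_concept_id), c(45619309L, 46000001L))
  expect_length(unique(res$pairs$provenance), 1)
  expect_equal(unique(res$pairs$evidence_type), "MEDLINE_MeSH_CR")

  # drug-side fan-out through a MeSH chemical with two RxNorm targets
  res <- normalize_record(list(mesh_chemical_code = "D999001",
                               mesh_disease_code = "D012206"), "CTD", v)
  expect_equal(sort(res$pairs$drug_concept_id), c(1539403L, 2000001L))

  # FAERS: two rows per pair, one per statistic
  res <- normalize_record(faers_record("36567", "10039020"), "FAERS", v)
  expect_equal(nrow(res$pairs), 2)
  expect_setequal(res$pairs$statistic_type, c("CASE_COUNT", "PRR"))
  expect_equal(res$pairs$statistic_value[res$pairs$statistic_type == "CASE_COUNT"], 12)
  expect_equal(res$pairs$statistic_value[res$pairs$statistic_type == "PRR"], 2.4)

  # rejection reason taxonomy
  expect_equal(normalize_record(spl_record("999999", "10039020"), "SPL_US", v)$rejection,
               "DRUG_UNMAPPED")
  expect_equal(normalize_record(spl_record("316672", "99999999"), "SPL_US", v)$rejection,
               "HOI_UNMAPPED")
  expect_equal(normalize_record(spl_record("999999", "99999999"), "SPL_US", v)$rejection,
               "BOTH_UNMAPPED")
  # clinical drug with no ingredient ancestor cannot form a valid pair
  expect_equal(normalize_record(spl_record("999001", "10039020"), "SPL_US", v)$rejection,
               "DRUG_UNMAPPED")

  # a record that does not match the kind's shape is a parse error
  expect_error(normalize_record(list(foo = 1), "SPL_US", v), "shape")
})

test_that("normalized pairs satisfy their invariants on every accepted record", {
  p <- shared_pipeline()
  bodies <- p$store$adr_body
  for (i in seq_len(nrow(bodies))) {
    ing <- ingredient_for(p$vocab, bodies$drug_concept_id[i])
    expect_true(bodies$ingredient_concept_id[i] %in% ing$concept_id)
    hoi <- get_concept(p$vocab, bodies$hoi_concept_id[i])
    expect_true(hoi$vocabulary_id == "SNOMED" && hoi$is_standard)
  }
})

test_that("run_etl reports coverage arithmetic at one decimal", {
  gen <- generate_vocabulary(6, 2, 8, seed = 11)
  src <- generate_source("SPL_US", gen$store, 20, 0.25, seed = 12, dir = tempfile())
  store <- evidence_store()
  rep <- run_etl("SPL_US", src$path, gen$store, store)
  expect_equal(rep$pairs_in_source, 20)
  expect_equal(rep$pairs_mapped, 15)
  expect_equal(rep$records_normalized + nrow(rep$rejects), rep$records_read)
  expect_setequal(rep$rejects$record_ref, src$unmappable_records)
  cov <- coverage_report(list(rep))
  expect_equal(cov$pct, 75.0)
  expect_equal(cov$pct_display, "75.0%")
})

test_that("run_etl handles empty input and reruns idempotently", {
  v <- tiny_vocab()
  empty_path <- tempfile(fileext = ".tsv")
  writeLines(paste(c("label_id", "set_id", "section_name",
                     "rxnorm_clinical_drug_code", "meddra_hoi_code",
                     "mention_text"), collapse = "\t"), empty_path)
  store <- evidence_store()
  rep <- run_etl("SPL_US", empty_path, v, store)
  expect_equal(rep$records_read, 0)
  expect_equal(rep$pairs_mapped, 0)
  expect_equal(length(store$annotations), 0)
  expect_equal(coverage_report(list(rep))$pct_display, "—")

  gen <- generate_vocabulary(4, 2, 5, seed = 13)
  src <- generate_source("FAERS", gen$store, 8, 0, seed = 14, dir = tempfile())
  store <- evidence_store()
  run_etl("FAERS", src$path, gen$store, store)
  n1 <- length(store$annotations)
  ev1 <- nrow(store$drug_hoi_evidence)
  run_etl("FAERS", src$path, gen$store, store)  # default replaces
  expect_equal(length(store$annotations), n1)
  expect_equal(nrow(store$drug_hoi_evidence), ev1)
  expect_error(run_etl("FAERS", src$path, gen$store, store, replace = FALSE),
               "already loaded")
})
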