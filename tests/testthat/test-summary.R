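# build a store from hand-written raw records for one kind
etl_records <- function(store, vocab, kind, records) {
  path <- tempfile(fileext = ".tsv")
  adrkb:::write_tsv_file(do.call(rbind, lapply(records, as.data.frame)), path)
  run_etl(kind, path, vocab, store)
}

test_that("evidence aggregation counts, sums, and passes PRR through", {
  v <- tiny_vocab()
  store <- evidence_store()
  # 3 annotations for one pair and one evidence type -> one RECORD_COUNT = 3
  etl_records(store, v, "MEDLINE_MESH", list(
    mesh_record("D019821", "D012206", pmid = "1"),
    mesh_record("D019821", "D012206", pmid = "2"),
    mesh_record("D019821", "D012206", pmid = "3")))
  ev <- store$drug_hoi_evidence
  expect_equal(nrow(ev), 1)
  expect_equal(ev$statistic_type, "RECORD_COUNT")
  expect_equal(ev$statistic_value, 3)
  expect_equal(ev$relationship_id, "1539403-45619309")

  # FAERS pair with count 12 and PRR 2.4 -> two records
  store2 <- evidence_store()
  etl_records(store2, v, "FAERS", list(faers_record("36567", "10039020", 12, 2.4)))
  ev2 <- store2$drug_hoi_evidence
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$statistic_value[ev2$statistic_type == "CASE_COUNT"], 12)
  expect_equal(ev2$statistic_value[ev2$statistic_type == "PRR"], 2.4)

  # two evidence types for one relationship -> two RECORD_COUNT records,
  # matching an independent group-by over the raw records
  store3 <- evidence_store()
  etl_records(store3, v, "MEDLINE_MESH", list(
    mesh_record("D019821", "D012206", "CASE_REPORT", pmid = "1"),
    mesh_record("D019821", "D012206", "CASE_REPORT", pmid = "2"),
    mesh_record("D019821", "D012206", "CLIN_TRIAL", pmid = "3")))
  ev3 <- store3$drug_hoi_evidence
  expect_equal(nrow(ev3), 2)
  expect_setequal(ev3$evidence_type, c("MEDLINE_MeSH_ClinTrial", "MEDLINE_MeSH_CR"))
  expect_equal(ev3$statistic_value[ev3$evidence_type == "MEDLINE_MeSH_CR"], 2)
  expect_equal(ev3$statistic_value[ev3$evidence_type == "MEDLINE_MeSH_ClinTrial"], 1)

  # conflicting PRR values for one pair in one source are ambiguous input
  store4 <- evidence_store()
  expect_error(
    etl_records(store4, v, "FAERS", list(faers_record("36567", "10039020", 5, 2.0),
                                         faers_record("36567", "10039020", 7, 3.0))),
    "conflicting PRR")
})

test_that("rollups aggregate clinical-drug evidence to the ingredient", {
  v <- tiny_vocab()
  store <- evidence_store()
  # one ingredient, two clinical drugs with counts 2 and 3, same HOI
  etl_records(store, v, "SPL_US", list(
    spl_record("316672", "10039020", label = "A1"),
    spl_record("316672", "10039020", label = "A2"),
    spl_record("316673", "10039020", label = "B1"),
    spl_record("316673", "10039020", label = "B2"),
    spl_record("316673", "10039020", label = "B3")))
  s <- build_rollups(store, v)
  l3 <- s[s$rollup_level == 3, ]
  expect_setequal(l3$aggregate_value, c(2, 3))
  expect_setequal(l3$clinical_drug_concept_id, c(1539411L, 1539412L))
  l1 <- s[s$rollup_level == 1, ]
  expect_equal(l1$aggregate_value, 5)
  expect_equal(l1$ingredient_concept_id, 1539403L)
  expect_true(all(is.na(l1$clinical_drug_concept_id)))
  expect_true(all(is.na(l1$hoi_concept_id)))
  expect_true(all(is.na(l3$hoi_concept_id)))

  # empty store -> empty summary
  expect_equal(nrow(build_rollups(evidence_store(), v)), 0)
})

test_that("ingredient-only stores have level 3 equal to level 4 projected", {
  v <- tiny_vocab()
  store <- evidence_store()
  etl_records(store, v, "MEDLINE_MESH", list(
    mesh_record("D019821", "D012206", pmid = "1"),
    mesh_record("D999001", "D012206", pmid = "2")))
  s <- build_rollups(store, v)
  l3 <- s[s$rollup_level == 3, c("ingredient_concept_id", "evidence_type",
                                 "statistic_type", "aggregate_value")]
  l4 <- s[s$rollup_level == 4, ]
  expect_true(all(is.na(l4$clinical_drug_concept_id)))
  proj <- stats::aggregate(l4$aggregate_value,
                           by = list(ingredient_concept_id = l4$ingredient_concept_id,
                                     evidence_type = l4$evidence_type,
                                     statistic_type = l4$statistic_type),
                           FUN = sum)
  ord <- function(df) df[order(df$ingredient_concept_id, df$evidence_type), ]
  expect_equal(ord(l3)$aggregate_value, ord(proj)$x)
})

test_that("PRR never appears above full detail", {
  p <- shared_pipeline()
  s <- build_rollups(p$store, p$vocab)
  expect_false(any(s$statistic_type == "PRR" & s$rollup_level < 4))
  expect_true(any(s$statistic_type == "PRR" & s$rollup_level == 4))
})

test_that("evidence whose drug lacks an ingredient is routed to rejects", {
  v <- tiny_vocab()
  store <- evidence_store()
  # force an evidence row for the orphan clinical drug directly
  store$drug_hoi_relationship <- data.frame(
    id = "2109999-45619309", drug_concept_id = 2109999L,
    rxnorm_drug = "Orphan 10 MG Oral Tablet", hoi_concept_id = 45619309L,
    snomed_hoi = "Rhabdomyolysis")
  store$drug_hoi_evidence <- data.frame(
    relationship_id = "2109999-45619309", source_id = "SPL_US",
    evidence_type = "SPL_SPLICER", modality = "SUPPORTS",
    statistic_type = "RECORD_COUNT", statistic_value = 1,
    evidence_linkout = "laertes://evidence?x")
  s <- build_rollups(store, v)
  expect_equal(nrow(s), 0)
  rej <- attr(s, "rejects")
  expect_equal(rej$relationship_id, "2109999-45619309")
  expect_equal(rej$reason, "NO_INGREDIENT")
})

test_that("overlap report equals exhaustive set algebra", {
  v <- tiny_vocab()
  # hand-planted pair sets over 2 ingredients x 2 conditions:
  #   A = {p1, p2, p3}, B = {p2, p3, p4}  -> union 4, intersection 2, 50.0%
  pairs <- data.frame(
    drug = c(1539403L, 1539403L, 2000001L, 2000001L),
    hoi = c(45619309L, 46000001L, 45619309L, 46000001L))
  store <- evidence_store()
  add_ev <- function(store, idx, source) {
    for (i in idx) {
      rid <- paste0(pairs$drug[i], "-", pairs$hoi[i])
      store$drug_hoi_relationship <- unique(rbind(
        store$drug_hoi_relationship,
        data.frame(id = rid, drug_concept_id = pairs$drug[i], rxnorm_drug = "x",
                   hoi_concept_id = pairs$hoi[i], snomed_hoi = "y")))
      store$drug_hoi_evidence <- rbind(
        store$drug_hoi_evidence,
        data.frame(relationship_id = rid, source_id = source,
                   evidence_type = "t", modality = "SUPPORTS",
                   statistic_type = "RECORD_COUNT", statistic_value = 1,
                   evidence_linkout = paste0("laertes://evidence?", source, i)))
    }
    store
  }
  store <- add_ev(store, 1:3, "SRC_A")
  store <- add_ev(store, 2:4, "SRC_B")
  ov <- overlap_report(store, list(A = "SRC_A", B = "SRC_B"), v)
  expect_equal(ov$n_union, 4)
  expect_equal(ov$n_intersection, 2)
  expect_equal(ov$pct_display, "50.0%")
  # identical pair sets from different sources -> 100.0%
  store <- add_ev(store, 1:3, "SRC_C")
  ov2 <- overlap_report(store, list(A = "SRC_A", C = "SRC_C"), v)
  expect_equal(ov2$pct_display, "100.0%")
  # disjoint pair sets -> 0.0%
  store <- add_ev(store, 4, "SRC_D")
  ov3 <- overlap_report(store, list(A = "SRC_A", D = "SRC_D"), v)
  expect_equal(ov3$pct_display, "0.0%")
  # overlapping group definitions are a usage error
  expect_error(overlap_report(store, list(A = "SRC_A", B = c("SRC_A", "SRC_B")), v),
               "disjoint")
})

test_that("negative-control search excludes any-evidence pairs", {
  p <- shared_pipeline()
  neg <- reserved_negative_pairs(p$vocab)
  ing_ids <- unique(c(neg$ingredient_concept_id,
                      p$suite$vocab_manifest$ingredients$concept_id))
  hoi_ids <- unique(c(neg$hoi_concept_id,
                      p$suite$vocab_manifest$conditions$concept_id))
  nc <- find_negative_controls(p$store, p$vocab, ing_ids, hoi_ids)
  key_nc <- paste(nc$ingredient_concept_id, nc$hoi_concept_id)
  # every reserved pair comes back
  expect_true(all(paste(neg$ingredient_concept_id, neg$hoi_concept_id) %in% key_nc))
  # no returned pair has any evidence (exhaustive scan over the bodies)
  body <- p$store$adr_body
  key_ev <- unique(paste(body$ingredient_concept_id, body$hoi_concept_id))
  expect_length(intersect(key_nc, key_ev), 0)
  # a pair with a single record is excluded
  covered <- p$suite$sources$CTD$planted_pairs[1, ]
  expect_false(paste(covered$ingredient_concept_id, covered$hoi_concept_id) %in% key_nc)
  # empty store -> full cross-product
  nc0 <- find_negative_controls(evidence_store(), p$vocab, ing_ids, hoi_ids)
  expect_equal(nrow(nc0), length(ing_ids) * length(hoi_ids))
  expect_error(find_negative_controls(p$store, p$vocab, 42L, hoi_ids),
               "unknown concept_id")
})
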