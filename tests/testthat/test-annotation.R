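make_ann <- function(kind, record, pairs, uid = 1L) {
  build_annotation(pairs, record, kind, uid)
}

test_that("annotation types and selectors follow the per-kind registry", {
  v <- tiny_vocab()
  pair <- normalize_record(mesh_record("D019821", "D012206"), "MEDLINE_MESH", v)$pairs
  a <- make_ann("MEDLINE_MESH", mesh_record("D019821", "D012206"), pair)
  expect_equal(a$annotation_type, "ohdsi:PubMedDrugHOIAnnotation")
  expect_equal(a$target$selector$exact_text, "A drug-event report.")
  expect_match(a$target$source_document_uri, "pubmed/20000001$")

  rec <- spl_record("316672", "10039020")
  pair <- normalize_record(rec, "SPL_US", v)$pairs
  a <- make_ann("SPL_US", rec, pair)
  expect_equal(a$target$selector$section, "ADVERSE REACTIONS")
  expect_null(a$target$selector$exact_text)

  rec <- faers_record("36567", "10039020")
  pairs <- normalize_record(rec, "FAERS", v)$pairs
  a <- make_ann("FAERS", rec, pairs)
  expect_length(a$target$selector, 0)
  expect_length(a$bodies, 2)  # one body per statistic type
})

test_that("HOI fan-out yields annotations sharing one source document", {
  v <- tiny_vocab()
  rec <- mesh_record("D019821", "D999002")  # maps to 2 SNOMED conditions
  store <- evidence_store()
  path <- tempfile(fileext = ".tsv")
  adrkb:::write_tsv_file(as.data.frame(rec), path)
  run_etl("MEDLINE_MESH", path, v, store)
  expect_length(store$annotations, 2)
  uris <- vapply(store$annotations, function(a) a$target$source_document_uri, "")
  expect_length(unique(uris), 1)
})

test_that("to_triples emits the fixed triple set", {
  v <- tiny_vocab()
  # 1 body, no selector -> exactly 7 triples
  rec <- list(mesh_chemical_code = "D019821", mesh_disease_code = "D012206")
  pair <- normalize_record(rec, "CTD", v)$pairs
  g <- to_triples(make_ann("CTD", rec, pair, uid = 5L))
  expect_equal(nrow(g), 7)
  preds <- basename(gsub("#", "/", g$predicate))
  expect_setequal(unique(preds),
                  c("type", "hasTarget", "hasSource", "hasBody", "ImedsDrug",
                    "ImedsHoi", "evidenceType"))
  # the body points at drug and HOI concept URIs in the ohdsi namespace
  expect_true(any(g$predicate == "http://purl.org/net/ohdsi#ImedsDrug" &
                    g$object == "http://purl.org/net/ohdsi#1539403"))
  expect_true(any(g$predicate == "http://purl.org/net/ohdsi#ImedsHoi" &
                    g$object == "http://purl.org/net/ohdsi#45619309"))
  # selector and extra bodies add their stated triples
  rec <- faers_record("36567", "10039020")
  g2 <- to_triples(make_ann("FAERS", rec, normalize_record(rec, "FAERS", v)$pairs))
  expect_equal(nrow(g2), 3 + 4 * 2)  # no selector, two bodies
  rec <- spl_record("316672", "10039020")
  g3 <- to_triples(make_ann("SPL_US", rec, normalize_record(rec, "SPL_US", v)$pairs))
  expect_equal(nrow(g3), 3 + 2 + 4)  # section selector adds 2
  # no blank nodes: every subject is a minted URI
  expect_true(all(grepl("^http", c(g$subject, g2$subject, g3$subject))))
})

test_that("Turtle and N-Triples serializations round-trip as sets", {
  p <- shared_pipeline()
  g <- store_to_graph(p$store)
  ttl <- tempfile(fileext = ".ttl")
  nt <- tempfile(fileext = ".nt")
  write_turtle(g, ttl)
  write_ntriples(g, nt)
  expect_true(graphs_equal(g, read_turtle(ttl)))
  expect_true(graphs_equal(g, read_turtle(nt)))
})

test_that("emitted Turtle is valid for an independent RDF parser", {
  v <- tiny_vocab()
  store <- evidence_store()
  recs <- rbind(as.data.frame(mesh_record("D019821", "D012206", pmid = "1")),
                as.data.frame(mesh_record("D999001", "D012206", pmid = "2")))
  path <- tempfile(fileext = ".tsv")
  adrkb:::write_tsv_file(recs, path)
  run_etl("MEDLINE_MESH", path, v, store)
  g <- store_to_graph(store)
  ttl <- tempfile(fileext = ".ttl")
  write_turtle(g, ttl)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import rdflib; g = rdflib.Graph(); g.parse('", ttl,
      "', format='turtle'); print(len(g))"))),
    stdout = TRUE, stderr = FALSE))
  expect_equal(as.integer(out[length(out)]), nrow(unique(g[, 1:3])))
})

test_that("relational rows are a lossless copy of the annotation", {
  v <- tiny_vocab()
  rec <- spl_record("316672", "10039020")
  a <- make_ann("SPL_US", rec, normalize_record(rec, "SPL_US", v)$pairs)
  rows <- to_relational(a)
  expect_equal(nrow(rows$adr_annotation), 1)
  expect_equal(nrow(rows$target), 1)
  expect_equal(nrow(rows$adr_body), 1)
  expect_equal(rebuild_from_relational(rows$adr_annotation, rows$target,
                                       rows$adr_body), a)
  # 2-body annotation -> 1 + 1 + 2 rows
  rec <- faers_record("36567", "10039020")
  a2 <- make_ann("FAERS", rec, normalize_record(rec, "FAERS", v)$pairs)
  rows2 <- to_relational(a2)
  expect_equal(nrow(rows2$adr_body), 2)
  expect_equal(rebuild_from_relational(rows2$adr_annotation, rows2$target,
                                       rows2$adr_body), a2)
})

test_that("rebuild inverts to_relational for every fixture annotation", {
  p <- shared_pipeline()
  rebuilt <- adrkb:::rebuild_all_annotations(p$store)
  expect_equal(length(rebuilt), length(p$store$annotations))
  for (k in names(p$store$annotations)) {
    expect_equal(rebuilt[[k]], p$store$annotations[[k]])
  }
})

test_that("query_annotations equals a brute-force scan for filter combinations", {
  p <- shared_pipeline()
  store <- p$store
  scan <- function(drug = NULL, hoi = NULL, type = NULL) {
    hits <- Filter(function(a) {
      if (!is.null(type) && a$annotation_type != type) return(FALSE)
      any(vapply(a$bodies, function(b) {
        ok <- TRUE
        if (!is.null(drug)) {
          ok <- ok && (b$drug_concept_id == drug || b$ingredient_concept_id == drug)
        }
        if (!is.null(hoi)) ok <- ok && b$hoi_concept_id == hoi
        ok
      }, logical(1)))
    }, store$annotations)
    sort(vapply(hits, function(a) a$annotation_uid, integer(1)))
  }
  uids <- function(x) unname(vapply(x, function(a) a$annotation_uid, integer(1)))
  body <- store$adr_body
  cases <- unique(body[seq(1, nrow(body), by = 7),
                       c("drug_concept_id", "hoi_concept_id")])
  for (i in seq_len(nrow(cases))) {
    d <- cases$drug_concept_id[i]; h <- cases$hoi_concept_id[i]
    expect_equal(uids(query_annotations(store, drug_concept_id = d)),
                 unname(scan(drug = d)))
    expect_equal(uids(query_annotations(store, drug_concept_id = d,
                                        hoi_concept_id = h)),
                 unname(scan(drug = d, hoi = h)))
  }
  for (ty in unique(store$adr_annotation$annotation_type)) {
    expect_equal(uids(query_annotations(store, annotation_type = ty)),
                 unname(scan(type = ty)))
  }
  expect_error(query_annotations(store), "at least one filter")
})

test_that("a clinical-drug filter does not match ingredient-level bodies", {
  v <- tiny_vocab()
  store <- evidence_store()
  # ingredient-level evidence only (MEDLINE), drug recorded as simvastatin
  path <- tempfile(fileext = ".tsv")
  adrkb:::write_tsv_file(as.data.frame(mesh_record("D019821", "D012206")), path)
  run_etl("MEDLINE_MESH", path, v, store)
  expect_length(query_annotations(store, drug_concept_id = 1539403), 1)
  expect_length(query_annotations(store, drug_concept_id = 1539411), 0)
})
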