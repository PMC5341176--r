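# Open Annotation evidence items: construction from normalized pairs, the
# relational (adr_annotation/target/adr_body) copy, and the drug/HOI/type
# query over the store.

# Per-kind registry: annotation type, selector style, identification method.
KIND_REGISTRY <- list(
  SPL_US = list(annotation_type = "ohdsi:SPLDrugHOIAnnotation",
                selector = "section", method_tag = "SPLICER-NLP",
                coverage_level = "CLINICAL_DRUG",
                title = "Adverse drug reactions mined from US product labels",
                coding = "RxNorm clinical drug / MedDRA HOI"),
  EU_SPC = list(annotation_type = "ohdsi:SPLDrugHOIAnnotation",
                selector = "section", method_tag = "PROTECT-manual",
                coverage_level = "INGREDIENT",
                title = "Adverse drug events from EU Summary of Product Characteristics",
                coding = "drug name / MedDRA HOI"),
  MEDLINE_MESH = list(annotation_type = "ohdsi:PubMedDrugHOIAnnotation",
                      selector = "exact_text", method_tag = "MeSH-coindex",
                      coverage_level = "INGREDIENT",
                      title = "MEDLINE drug-HOI evidence by MeSH co-indexing",
                      coding = "MeSH drug / MeSH HOI"),
  MEDLINE_SEMMED = list(annotation_type = "ohdsi:PubMedDrugHOIAnnotation",
                        selector = "exact_text", method_tag = "SemRep-NLP",
                        coverage_level = "INGREDIENT",
                        title = "Semantic MEDLINE sentence-span drug-HOI evidence",
                        coding = "UMLS CUI drug / UMLS CUI HOI"),
  FAERS = list(annotation_type = "ohdsi:FAERSDrugHOIAnnotation",
               selector = "none", method_tag = "FAERS-disproportionality",
               coverage_level = "INGREDIENT",
               title = "Spontaneous report counts and PRR",
               coding = "RxNorm ingredient / MedDRA HOI"),
  CTD = list(annotation_type = "ohdsi:CTDDrugHOIAnnotation",
             selector = "none", method_tag = "CTD-curation",
             coverage_level = "INGREDIENT",
             title = "Chemical-disease associations",
             coding = "MeSH chemical / MeSH disease")
)

# Document URI minted from the record's native identifier.
document_uri <- function(kind, record) {
  switch(kind,
    SPL_US = paste0(NS_OHDSI, "spl/", record$set_id),
    EU_SPC = paste0(NS_OHDSI, "euspc/", record$doc_id),
    MEDLINE_MESH = paste0("http://www.ncbi.nlm.nih.gov/pubmed/", record$pmid),
    MEDLINE_SEMMED = paste0("http://www.ncbi.nlm.nih.gov/pubmed/", record$pmid),
    FAERS = paste0(NS_OHDSI, "faers/", record$drug_code, "-", record$hoi_code),
    CTD = paste0(NS_OHDSI, "ctd/", record$mesh_chemical_code, "-",
                 record$mesh_disease_code)
  )
}

#' Build one Open Annotation item for a normalized drug-HOI pair
#'
#' The annotation's type comes from the per-kind registry; its target URI is
#' minted from the record's document identifier; the selector carries the
#' exact text for MEDLINE kinds and the label section for label kinds (none
#' for FAERS/CTD). `pair` may hold several rows sharing one (drug, HOI) when a
#' source contributes more than one evidence type per record (FAERS count and
#' PRR): each row becomes one body.
#'
#' @param pair one (drug, HOI) group of normalized-pair rows (see
#'   [normalize_record()]).
#' @param record the raw source record (named list / one-row data frame).
#' @param kind the source kind.
#' @param annotation_uid integer uid to mint the annotation under.
#' @return An `oa_annotation` object.
#' @export
build_annotation <- function(pair, record, kind, annotation_uid) {
  reg <- KIND_REGISTRY[[kind]]
  if (is.null(reg)) stop("no annotation type registered for kind ", kind, call. = FALSE)
  pair <- as.data.frame(pair)
  stopifnot(nrow(pair) >= 1,
            length(unique(pair$drug_concept_id)) == 1,
            length(unique(pair$hoi_concept_id)) == 1)
  selector <- switch(reg$selector,
    exact_text = list(exact_text = as.character(record$title_abstract_text %||%
                                                  record$sentence_span)),
    section = list(section = as.character(record$section_name %||%
                                            "UNDESIRABLE EFFECTS")),
    none = list()
  )
  bodies <- lapply(seq_len(nrow(pair)), function(i) {
    list(drug_concept_id = as.integer(pair$drug_concept_id[i]),
         ingredient_concept_id = as.integer(pair$ingredient_concept_id[i]),
         hoi_concept_id = as.integer(pair$hoi_concept_id[i]),
         evidence_type = pair$evidence_type[i],
         method_tag = reg$method_tag)
  })
  structure(
    list(annotation_uid = as.integer(annotation_uid),
         annotation_type = reg$annotation_type,
         kind = kind,
         source_id = kind,
         target = list(source_document_uri = document_uri(kind, record),
                       selector = selector),
         bodies = bodies),
    class = "oa_annotation"
  )
}

#' @export
print.oa_annotation <- function(x, ...) {
  cat("<oa_annotation #", x$annotation_uid, "> ", x$annotation_type, ", ",
      length(x$bodies), " body(ies), target ", x$target$source_document_uri,
      "\n", sep = "")
  invisible(x)
}

#' Convert an annotation to its relational rows
#'
#' One `adr_annotation` row, one `target` row, and one `adr_body` row per
#' body. Lossless: [rebuild_from_relational()] inverts it.
#'
#' @param annotation an `oa_annotation`.
#' @return Named list of data frames `adr_annotation`, `target`, `adr_body`.
#' @export
to_relational <- function(annotation) {
  a <- annotation
  sel <- a$target$selector
  list(
    adr_annotation = data.frame(
      annotation_uid = a$annotation_uid, annotation_type = a$annotation_type,
      source_id = a$source_id, kind = a$kind),
    target = data.frame(
      annotation_uid = a$annotation_uid,
      source_document_uri = a$target$source_document_uri,
      exact_text = sel$exact_text %||% NA_character_,
      section = sel$section %||% NA_character_),
    adr_body = do.call(rbind, lapply(seq_along(a$bodies), function(i) {
      b <- a$bodies[[i]]
      data.frame(annotation_uid = a$annotation_uid, body_index = i,
                 drug_concept_id = b$drug_concept_id,
                 ingredient_concept_id = b$ingredient_concept_id,
                 hoi_concept_id = b$hoi_concept_id,
                 evidence_type = b$evidence_type, method_tag = b$method_tag)
    }))
  )
}

#' Rebuild an annotation object from its relational rows
#'
#' @param ann_row one `adr_annotation` row.
#' @param target_row the matching `target` row.
#' @param body_rows the matching `adr_body` rows (>= 1).
#' @return An `oa_annotation` equal to the one [to_relational()] flattened.
#' @export
rebuild_from_relational <- function(ann_row, target_row, body_rows) {
  body_rows <- body_rows[order(body_rows$body_index), , drop = FALSE]
  selector <- list()
  if (!is.na(target_row$exact_text)) selector$exact_text <- target_row$exact_text
  if (!is.na(target_row$section)) selector$section <- target_row$section
  structure(
    list(annotation_uid = as.integer(ann_row$annotation_uid),
         annotation_type = ann_row$annotation_type,
         kind = ann_row$kind,
         source_id = ann_row$source_id,
         target = list(source_document_uri = target_row$source_document_uri,
                       selector = selector),
         bodies = lapply(seq_len(nrow(body_rows)), function(i) {
           list(drug_concept_id = as.integer(body_rows$drug_concept_id[i]),
                ingredient_concept_id = as.integer(body_rows$ingredient_concept_id[i]),
                hoi_concept_id = as.integer(body_rows$hoi_concept_id[i]),
                evidence_type = body_rows$evidence_type[i],
                method_tag = body_rows$method_tag[i])
         })),
    class = "oa_annotation"
  )
}

rebuild_all_annotations <- function(store) {
  anns <- list()
  if (nrow(store$adr_annotation) == 0) return(anns)
  for (i in seq_len(nrow(store$adr_annotation))) {
    ann_row <- store$adr_annotation[i, , drop = FALSE]
    uid <- ann_row$annotation_uid
    anns[[as.character(uid)]] <- rebuild_from_relational(
      ann_row,
      store$target[store$target$annotation_uid == uid, , drop = FALSE][1, , drop = FALSE],
      store$adr_body[store$adr_body$annotation_uid == uid, , drop = FALSE])
  }
  anns
}

# Append an annotation to the store (object + relational copy).
add_annotation <- function(store, annotation) {
  rows <- to_relational(annotation)
  store$adr_annotation <- rbind(store$adr_annotation, rows$adr_annotation)
  store$target <- rbind(store$target, rows$target)
  store$adr_body <- rbind(store$adr_body, rows$adr_body)
  store$annotations[[as.character(annotation$annotation_uid)]] <- annotation
  invisible(store)
}

#' Query annotations by drug, HOI, type, evidence type, or source
#'
#' Returns the annotations having at least one body matching all supplied
#' filters. The drug filter matches exactly on either drug-level field of the
#' body (`drug_concept_id` or `ingredient_concept_id`); it performs no
#' ingredient expansion, so filtering by a clinical drug does not return
#' annotations recorded only at its ingredient level (rollups own that
#' semantics).
#'
#' @param store an `evidence_store`.
#' @param drug_concept_id,hoi_concept_id,annotation_type,evidence_type,source_id
#'   optional filters; at least one must be given.
#' @return List of `oa_annotation`, ordered by `annotation_uid`.
#' @export
query_annotations <- function(store, drug_concept_id = NULL, hoi_concept_id = NULL,
                              annotation_type = NULL, evidence_type = NULL,
                              source_id = NULL) {
  if (is.null(drug_concept_id) && is.null(hoi_concept_id) &&
      is.null(annotation_type) && is.null(evidence_type) && is.null(source_id)) {
    stop("query_annotations requires at least one filter", call. = FALSE)
  }
  bodies <- store$adr_body
  keep <- rep(TRUE, nrow(bodies))
  if (!is.null(drug_concept_id)) {
    d <- as.integer(drug_concept_id)
    keep <- keep & (bodies$drug_concept_id == d | bodies$ingredient_concept_id == d)
  }
  if (!is.null(hoi_concept_id)) {
    keep <- keep & bodies$hoi_concept_id == as.integer(hoi_concept_id)
  }
  if (!is.null(evidence_type)) {
    keep <- keep & bodies$evidence_type == evidence_type
  }
  uids <- unique(bodies$annotation_uid[keep])
  ann_tab <- store$adr_annotation
  meta_keep <- ann_tab$annotation_uid %in% uids
  if (!is.null(annotation_type)) {
    meta_keep <- meta_keep & ann_tab$annotation_type == annotation_type
  }
  if (!is.null(source_id)) {
    meta_keep <- meta_keep & ann_tab$source_id == source_id
  }
  uids <- sort(ann_tab$annotation_uid[meta_keep])
  store$annotations[as.character(uids)]
}

#' Render annotations as JSON
#'
#' One object per annotation with stable field order: uid, type, target
#' (uri + selector), bodies.
#'
#' @param annotations list of `oa_annotation`.
#' @return A JSON string.
#' @export
annotations_to_json <- function(annotations) {
  objs <- lapply(annotations, function(a) {
    list(annotation_uid = a$annotation_uid,
         annotation_type = a$annotation_type,
         target = list(uri = a$target$source_document_uri,
                       selector = if (length(a$target$selector) == 0) NULL else a$target$selector),
         bodies = a$bodies)
  })
  jsonlite::toJSON(objs, auto_unbox = TRUE, null = "null", pretty = TRUE)
}
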