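# The evidence store: relational tables named after the summary-schema
# convention (evidence_sources, drug_hoi_relationship, drug_hoi_evidence,
# laertes_summary) plus the Open Annotation copies (adr_annotation, target,
# adr_body), linkout maps, and ETL bookkeeping. Held as data frames in an
# environment; persisted as a directory of TSV tables.

STORE_TABLES <- c("evidence_sources", "adr_annotation", "target", "adr_body",
                  "drug_hoi_relationship", "drug_hoi_evidence",
                  "laertes_summary", "linkout_map", "linkout_annotation",
                  "etl_report", "etl_reject")

#' Create an empty evidence store
#'
#' @return An environment of class `evidence_store` holding the relational
#'   tables and the in-memory annotation objects.
#' @export
evidence_store <- function() {
  store <- new.env(parent = emptyenv())
  store$evidence_sources <- empty_df(
    source_id = "character", title = "character", coverage_level = "character",
    coding = "character", version_tag = "character")
  store$adr_annotation <- empty_df(
    annotation_uid = "integer", annotation_type = "character",
    source_id = "character", kind = "character")
  store$target <- empty_df(
    annotation_uid = "integer", source_document_uri = "character",
    exact_text = "character", section = "character")
  store$adr_body <- empty_df(
    annotation_uid = "integer", body_index = "integer",
    drug_concept_id = "integer", ingredient_concept_id = "integer",
    hoi_concept_id = "integer", evidence_type = "character",
    method_tag = "character")
  store$drug_hoi_relationship <- empty_df(
    id = "character", drug_concept_id = "integer", rxnorm_drug = "character",
    hoi_concept_id = "integer", snomed_hoi = "character")
  store$drug_hoi_evidence <- empty_df(
    relationship_id = "character", source_id = "character",
    evidence_type = "character", modality = "character",
    statistic_type = "character", statistic_value = "numeric",
    evidence_linkout = "character")
  store$laertes_summary <- empty_df(
    rollup_level = "integer", ingredient_concept_id = "integer",
    clinical_drug_concept_id = "integer", hoi_concept_id = "integer",
    evidence_type = "character", statistic_type = "character",
    aggregate_value = "numeric")
  store$linkout_map <- empty_df(short_key = "character", long_url = "character")
  store$linkout_annotation <- empty_df(
    short_key = "character", annotation_uid = "integer")
  store$etl_report <- empty_df(
    source_id = "character", records_read = "integer",
    records_normalized = "integer", pairs_in_source = "integer",
    pairs_mapped = "integer")
  store$etl_reject <- empty_df(
    source_id = "character", record_ref = "character", reason = "character")
  store$annotations <- list()   # oa_annotation objects keyed by uid (as character)
  store$next_annotation_uid <- 1L
  store$next_linkout_counter <- 0L
  class(store) <- c("evidence_store", "environment")
  store
}

#' @export
print.evidence_store <- function(x, ...) {
  cat("<evidence_store> ", length(x$annotations), " annotations, ",
      nrow(x$drug_hoi_evidence), " evidence records, ",
      nrow(x$laertes_summary), " summary rows\n", sep = "")
  invisible(x)
}

next_annotation_uid <- function(store) {
  uid <- store$next_annotation_uid
  store$next_annotation_uid <- uid + 1L
  uid
}

#' Persist an evidence store as a directory of TSV tables
#'
#' Annotation objects are not written separately: they are rebuilt losslessly
#' from the relational `adr_annotation`/`target`/`adr_body` rows on open.
#' Tables are written sorted by key so a rebuilt store exports byte-identically.
#'
#' @param store an `evidence_store`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_evidence_store <- function(store, dir) {
  stopifnot(inherits(store, "evidence_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in STORE_TABLES) {
    df <- store[[tab]]
    if (nrow(df) > 0) {
      df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
    }
    write_tsv_file(df, file.path(dir, paste0(tab, ".tsv")))
  }
  invisible(dir)
}

#' Reopen a persisted evidence store
#'
#' Restores all tables, rebuilds the annotation objects from their relational
#' rows, and recovers the uid/linkout counters from the persisted keys.
#'
#' @param dir directory previously written by [save_evidence_store()].
#' @return An `evidence_store`.
#' @export
open_evidence_store <- function(dir) {
  store <- evidence_store()
  for (tab in STORE_TABLES) {
    path <- file.path(dir, paste0(tab, ".tsv"))
    if (!file.exists(path)) stop("store table missing: ", path, call. = FALSE)
    raw <- read_tsv_file(path)
    proto <- store[[tab]]
    for (nm in names(proto)) {
      v <- raw[[nm]]
      v[v == ""] <- NA
      store_col <- proto[[nm]]
      raw[[nm]] <- if (is.integer(store_col)) as.integer(v)
        else if (is.numeric(store_col)) as.numeric(v)
        else as.character(v)
    }
    store[[tab]] <- raw[, names(proto), drop = FALSE]
  }
  # rebuild annotation objects and counters
  store$annotations <- rebuild_all_annotations(store)
  store$next_annotation_uid <- if (nrow(store$adr_annotation) == 0) 1L else
    max(store$adr_annotation$annotation_uid) + 1L
  store$next_linkout_counter <- if (nrow(store$linkout_map) == 0) 0L else
    as.integer(max(vapply(store$linkout_map$short_key, base62_decode, numeric(1))) + 1)
  store
}

#' Register (or replace) an evidence source's metadata
#' @param store an `evidence_store`.
#' @param source_id short unique key, e.g. `"MEDLINE_MESH"`.
#' @param title human-readable description.
#' @param coverage_level `"CLINICAL_DRUG"` or `"INGREDIENT"`.
#' @param coding description of the native terminologies.
#' @param version_tag version string of the loaded extract.
#' @return `store`, invisibly.
#' @export
register_source <- function(store, source_id, title, coverage_level, coding,
                            version_tag = "v1") {
  stopifnot(coverage_level %in% c("CLINICAL_DRUG", "INGREDIENT"))
  es <- store$evidence_sources
  es <- es[es$source_id != source_id, , drop = FALSE]
  store$evidence_sources <- rbind(es, data.frame(
    source_id = source_id, title = title, coverage_level = coverage_level,
    coding = coding, version_tag = version_tag))
  invisible(store)
}

# Drop every row belonging to one source (annotations, evidence, linkouts,
# reports) ahead of a replacing reload.
purge_source <- function(store, source_id) {
  uids <- store$adr_annotation$annotation_uid[store$adr_annotation$source_id == source_id]
  store$adr_annotation <- store$adr_annotation[!store$adr_annotation$source_id == source_id, , drop = FALSE]
  store$target <- store$target[!store$target$annotation_uid %in% uids, , drop = FALSE]
  store$adr_body <- store$adr_body[!store$adr_body$annotation_uid %in% uids, , drop = FALSE]
  store$annotations[as.character(uids)] <- NULL
  ev <- store$drug_hoi_evidence
  gone_keys <- character(0)
  if (nrow(ev) > 0) {
    gone <- ev$source_id == source_id
    gone_urls <- ev$evidence_linkout[gone]
    store$drug_hoi_evidence <- ev[!gone, , drop = FALSE]
    gone_keys <- store$linkout_map$short_key[store$linkout_map$long_url %in% gone_urls]
    store$linkout_map <- store$linkout_map[!store$linkout_map$long_url %in% gone_urls, , drop = FALSE]
    store$linkout_annotation <- store$linkout_annotation[
      !store$linkout_annotation$short_key %in% gone_keys, , drop = FALSE]
  }
  # relationships no longer referenced by any evidence
  keep_rel <- unique(store$drug_hoi_evidence$relationship_id)
  store$drug_hoi_relationship <- store$drug_hoi_relationship[
    store$drug_hoi_relationship$id %in% keep_rel, , drop = FALSE]
  store$etl_report <- store$etl_report[store$etl_report$source_id != source_id, , drop = FALSE]
  store$etl_reject <- store$etl_reject[store$etl_reject$source_id != source_id, , drop = FALSE]
  invisible(store)
}
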