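# Per-source ETL: normalize raw records to standard (RxNorm drug, SNOMED HOI)
# pairs via the kind-specific terminology route, build annotations, load them,
# and derive aggregated statistics with linkouts — the
# transform / load / derive pattern, one adapter per source shape.

REQUIRED_COLUMNS <- list(
  SPL_US = c("label_id", "set_id", "section_name", "rxnorm_clinical_drug_code",
             "meddra_hoi_code", "mention_text"),
  EU_SPC = c("doc_id", "drug_name", "meddra_hoi_code"),
  MEDLINE_MESH = c("pmid", "mesh_drug_code", "mesh_hoi_code", "pub_type",
                   "title_abstract_text"),
  MEDLINE_SEMMED = c("pmid", "cui_drug", "cui_hoi", "sentence_span", "pub_type"),
  FAERS = c("drug_code", "hoi_code", "case_count", "prr"),
  CTD = c("mesh_chemical_code", "mesh_disease_code")
)

#' Evidence-type tag for a source kind
#'
#' Returns the summary-store evidence-type string: `MEDLINE_MeSH_CR` /
#' `MEDLINE_MeSH_ClinTrial` / `MEDLINE_MeSH_Other` (and the `SemMedDB`
#' equivalents) keyed by publication type, `SPL_EU_SPC` for EU labels,
#' `SPL_SPLICER` for US labels, `CTD_ChemicalDisease`, and for spontaneous
#' reports `FAERS_CaseCount` or `FAERS_PRR` keyed by statistic type.
#'
#' @param kind source kind.
#' @param pub_type publication type (`CLIN_TRIAL`, `CASE_REPORT`, `OTHER`);
#'   required for the MEDLINE kinds.
#' @param statistic_type `CASE_COUNT` or `PRR`; required for FAERS.
#' @return The evidence-type string.
#' @export
evidence_type_for <- function(kind, pub_type = NULL, statistic_type = NULL) {
  kind <- match.arg(kind, SOURCE_KINDS)
  if (kind %in% c("MEDLINE_MESH", "MEDLINE_SEMMED")) {
    if (is.null(pub_type)) {
      stop("pub_type is required for MEDLINE kinds", call. = FALSE)
    }
    pub_type <- match.arg(pub_type, PUB_TYPES)
    stem <- if (kind == "MEDLINE_MESH") "MEDLINE_MeSH_" else "MEDLINE_SemMedDB_"
    return(paste0(stem, switch(pub_type, CASE_REPORT = "CR",
                               CLIN_TRIAL = "ClinTrial", OTHER = "Other")))
  }
  switch(kind,
    SPL_US = "SPL_SPLICER",
    EU_SPC = "SPL_EU_SPC",
    CTD = "CTD_ChemicalDisease",
    FAERS = {
      if (is.null(statistic_type)) {
        stop("statistic_type is required for FAERS", call. = FALSE)
      }
      switch(match.arg(statistic_type, c("CASE_COUNT", "PRR")),
             CASE_COUNT = "FAERS_CaseCount", PRR = "FAERS_PRR")
    }
  )
}

#' All evidence-type tags the shipped adapters can emit
#' @return Character vector of valid tags.
#' @export
known_evidence_types <- function() {
  c("SPL_SPLICER", "SPL_EU_SPC",
    "MEDLINE_MeSH_CR", "MEDLINE_MeSH_ClinTrial", "MEDLINE_MeSH_Other",
    "MEDLINE_SemMedDB_CR", "MEDLINE_SemMedDB_ClinTrial", "MEDLINE_SemMedDB_Other",
    "FAERS_CaseCount", "FAERS_PRR", "CTD_ChemicalDisease")
}

pair_row <- function(drug, ingredient, hoi, evidence_type, statistic_type,
                     statistic_value, provenance) {
  data.frame(drug_concept_id = as.integer(drug),
             ingredient_concept_id = as.integer(ingredient),
             hoi_concept_id = as.integer(hoi),
             evidence_type = evidence_type,
             modality = "SUPPORTS",
             statistic_type = statistic_type,
             statistic_value = as.numeric(statistic_value),
             provenance = provenance)
}

rejection <- function(reason, ref) list(pairs = NULL, rejection = reason, record_ref = ref)
acceptance <- function(pairs, ref) list(pairs = pairs, rejection = NULL, record_ref = ref)

# resolve the drug side to (drug_concept_id, ingredient_concept_id) rows
resolve_drug <- function(record, kind, vocab, options) {
  switch(kind,
    SPL_US = {
      hit <- concept_by_code(vocab, "RXNORM", record$rxnorm_clinical_drug_code)
      if (is.null(hit)) return(NULL)
      ing <- ingredient_for(vocab, hit$concept_id)
      if (nrow(ing) == 0) return(NULL)
      data.frame(drug_concept_id = hit$concept_id,
                 ingredient_concept_id = ing$concept_id)
    },
    EU_SPC = {
      hits <- match_drug_by_name(vocab, record$drug_name,
                                 strip_salts = isTRUE(options$strip_salts %||% TRUE))
      if (nrow(hits) == 0) return(NULL)
      data.frame(drug_concept_id = hits$concept_id,
                 ingredient_concept_id = hits$concept_id)
    },
    MEDLINE_MESH = ,
    CTD = {
      code <- if (kind == "CTD") record$mesh_chemical_code else record$mesh_drug_code
      src <- concept_by_code(vocab, "MESH", code)
      if (is.null(src)) return(NULL)
      std <- map_to_standard(vocab, src$concept_id, "RXNORM")
      if (nrow(std) == 0) return(NULL)
      data.frame(drug_concept_id = std$concept_id,
                 ingredient_concept_id = std$concept_id)
    },
    MEDLINE_SEMMED = {
      cid <- options$crosswalk$concept_id[options$crosswalk$cui == record$cui_drug]
      if (length(cid) == 0) return(NULL)
      concept <- get_concept(vocab, cid[1])
      std <- if (concept$vocabulary_id == "RXNORM" && isTRUE(concept$is_standard)) {
        concept
      } else {
        map_to_standard(vocab, concept$concept_id, "RXNORM")
      }
      if (nrow(std) == 0) return(NULL)
      data.frame(drug_concept_id = std$concept_id,
                 ingredient_concept_id = std$concept_id)
    },
    FAERS = {
      hit <- concept_by_code(vocab, "RXNORM", record$drug_code)
      if (is.null(hit)) return(NULL)
      ing <- ingredient_for(vocab, hit$concept_id)
      if (nrow(ing) == 0) return(NULL)
      data.frame(drug_concept_id = ing$concept_id,
                 ingredient_concept_id = ing$concept_id)
    }
  )
}

# resolve the HOI side to standard SNOMED condition ids
resolve_hoi <- function(record, kind, vocab, options) {
  std <- switch(kind,
    SPL_US = ,
    EU_SPC = ,
    FAERS = {
      code <- record$meddra_hoi_code %||% record$hoi_code
      src <- concept_by_code(vocab, "MEDDRA", code)
      if (is.null(src)) return(integer(0))
      map_to_standard(vocab, src$concept_id, "SNOMED")$concept_id
    },
    MEDLINE_MESH = ,
    CTD = {
      code <- if (kind == "CTD") record$mesh_disease_code else record$mesh_hoi_code
      src <- concept_by_code(vocab, "MESH", code)
      if (is.null(src)) return(integer(0))
      map_to_standard(vocab, src$concept_id, "SNOMED")$concept_id
    },
    MEDLINE_SEMMED = {
      cid <- options$crosswalk$concept_id[options$crosswalk$cui == record$cui_hoi]
      if (length(cid) == 0) return(integer(0))
      concept <- get_concept(vocab, cid[1])
      if (concept$vocabulary_id == "SNOMED" && isTRUE(concept$is_standard)) {
        concept$concept_id
      } else {
        map_to_standard(vocab, concept$concept_id, "SNOMED")$concept_id
      }
    }
  )
  sort(as.integer(std))
}

#' Normalize one raw record to standard drug-HOI pairs
#'
#' Resolves the drug by the kind's route (RxNorm code lookup plus
#' ingredient expansion for US labels; exact name match for EU SPC; MeSH ->
#' RxNorm for MEDLINE MeSH and CTD; CUI crosswalk then mapping for Semantic
#' MEDLINE; direct code lookup for FAERS) and the HOI via MedDRA/MeSH ->
#' SNOMED mapping. Mapping fan-out yields one pair per (drug target x HOI
#' target); FAERS emits two rows per pair (case count and PRR). Mapping misses
#' yield a rejection with reason `DRUG_UNMAPPED`, `HOI_UNMAPPED` or
#' `BOTH_UNMAPPED`; a record that does not match the kind's column shape is a
#' parse error, not a rejection.
#'
#' @param record named list or one-row data frame in the kind's shape.
#' @param kind source kind.
#' @param vocab a `vocab_store`.
#' @param options list; `strip_salts` (EU SPC), `crosswalk` data frame
#'   (Semantic MEDLINE).
#' @return List with `pairs` (data frame or `NULL`), `rejection` (reason or
#'   `NULL`) and `record_ref`.
#' @export
normalize_record <- function(record, kind, vocab, options = list()) {
  kind <- match.arg(kind, SOURCE_KINDS)
  record <- as.list(record)
  missing_cols <- setdiff(REQUIRED_COLUMNS[[kind]], names(record))
  if (length(missing_cols) > 0) {
    stop("record does not match ", kind, " shape; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ref <- record_ref(kind, record, options$row %||% NA)
  drug <- resolve_drug(record, kind, vocab, options)
  hoi <- resolve_hoi(record, kind, vocab, options)
  if (is.null(drug) && length(hoi) == 0) return(rejection("BOTH_UNMAPPED", ref))
  if (is.null(drug)) return(rejection("DRUG_UNMAPPED", ref))
  if (length(hoi) == 0) return(rejection("HOI_UNMAPPED", ref))

  combos <- expand.grid(d = seq_len(nrow(drug)), h = seq_along(hoi))
  pairs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    d <- combos$d[i]; h <- combos$h[i]
    if (kind == "FAERS") {
      rbind(
        pair_row(drug$drug_concept_id[d], drug$ingredient_concept_id[d], hoi[h],
                 evidence_type_for("FAERS", statistic_type = "CASE_COUNT"),
                 "CASE_COUNT", record$case_count, ref),
        pair_row(drug$drug_concept_id[d], drug$ingredient_concept_id[d], hoi[h],
                 evidence_type_for("FAERS", statistic_type = "PRR"),
                 "PRR", record$prr, ref)
      )
    } else {
      et <- evidence_type_for(kind, pub_type = record$pub_type)
      pair_row(drug$drug_concept_id[d], drug$ingredient_concept_id[d], hoi[h],
               et, "RECORD_COUNT", 1, ref)
    }
  }))
  acceptance(pairs, ref)
}

# native-level distinct pair key of one raw record, for coverage accounting
native_pair_key <- function(record, kind) {
  switch(kind,
    SPL_US = paste(record$rxnorm_clinical_drug_code, record$meddra_hoi_code),
    EU_SPC = paste(normalize_name(record$drug_name), record$meddra_hoi_code),
    MEDLINE_MESH = paste(record$mesh_drug_code, record$mesh_hoi_code),
    MEDLINE_SEMMED = paste(record$cui_drug, record$cui_hoi),
    FAERS = paste(record$drug_code, record$hoi_code),
    CTD = paste(record$mesh_chemical_code, record$mesh_disease_code)
  )
}

#' Run the full ETL for one raw source file
#'
#' Transform (normalize every record), load (one annotation per accepted
#' record and distinct (drug, HOI); FAERS annotations carry one body per
#' statistic), then derive (aggregated evidence records and linkouts). The
#' operation is idempotent per `(source_id, version_tag)`: by default a rerun
#' replaces the source's previous rows; with `replace = FALSE` a duplicate
#' load is an error.
#'
#' @param kind source kind (doubles as `source_id`).
#' @param raw_path path to the raw tab-delimited file.
#' @param vocab a `vocab_store`.
#' @param store an `evidence_store`.
#' @param options adapter options (see [normalize_record()]); for
#'   `MEDLINE_SEMMED`, `crosswalk_path` may name the CUI crosswalk file
#'   (defaults to `UMLS_CROSSWALK.tsv` beside the raw file).
#' @param version_tag version string recorded in `evidence_sources`.
#' @param replace replace an existing load of the same source?
#' @return An `etl_report` list: `source_id`, `records_read`,
#'   `records_normalized`, `pairs_in_source`, `pairs_mapped`, `rejects`.
#' @export
run_etl <- function(kind, raw_path, vocab, store, options = list(),
                    version_tag = "v1", replace = TRUE) {
  kind <- match.arg(kind, SOURCE_KINDS)
  raw <- read_tsv_file(raw_path)
  missing_cols <- setdiff(REQUIRED_COLUMNS[[kind]], names(raw))
  if (length(missing_cols) > 0) {
    stop("raw file does not match ", kind, " shape; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (kind == "MEDLINE_SEMMED" && is.null(options$crosswalk)) {
    xw_path <- options$crosswalk_path %||%
      file.path(dirname(raw_path), "UMLS_CROSSWALK.tsv")
    if (!file.exists(xw_path)) {
      stop("Semantic MEDLINE requires a CUI crosswalk file: ", xw_path, call. = FALSE)
    }
    xw <- read_tsv_file(xw_path)
    xw$concept_id <- as.integer(xw$concept_id)
    options$crosswalk <- xw
  }
  already <- store$evidence_sources$source_id == kind
  if (any(already)) {
    if (!replace) {
      stop("source ", kind, " (", version_tag,
           ") already loaded; pass replace = TRUE to reload", call. = FALSE)
    }
    purge_source(store, kind)
  }
  reg <- KIND_REGISTRY[[kind]]
  register_source(store, kind, reg$title, reg$coverage_level, reg$coding,
                  version_tag)

  all_pairs <- list()
  annotations <- list()
  rejects <- list()
  records_normalized <- 0L
  mapped_keys <- character(0)
  for (r in seq_len(nrow(raw))) {
    record <- as.list(raw[r, , drop = FALSE])
    options$row <- r
    res <- normalize_record(record, kind, vocab, options)
    if (!is.null(res$rejection)) {
      rejects[[length(rejects) + 1]] <- data.frame(
        source_id = kind, record_ref = res$record_ref, reason = res$rejection)
      next
    }
    records_normalized <- records_normalized + 1L
    pairs <- res$pairs
    all_pairs[[length(all_pairs) + 1]] <- pairs
    # native-level mapped pair (clinical drug for SPL_US, ingredient otherwise)
    mapped_keys <- c(mapped_keys, unique(paste(pairs$drug_concept_id,
                                               pairs$hoi_concept_id)))
    groups <- unique(pairs[, c("drug_concept_id", "hoi_concept_id")])
    for (g in seq_len(nrow(groups))) {
      grp <- pairs[pairs$drug_concept_id == groups$drug_concept_id[g] &
                     pairs$hoi_concept_id == groups$hoi_concept_id[g], , drop = FALSE]
      ann <- build_annotation(grp, record, kind, next_annotation_uid(store))
      add_annotation(store, ann)
      annotations[[length(annotations) + 1]] <- ann
    }
  }
  pairs_df <- if (length(all_pairs) > 0) do.call(rbind, all_pairs) else NULL
  if (!is.null(pairs_df)) {
    aggregate_evidence(store, pairs_df, annotations, kind, vocab)
  }
  native_keys <- vapply(seq_len(nrow(raw)), function(r)
    native_pair_key(as.list(raw[r, , drop = FALSE]), kind), "")
  report <- structure(list(
    source_id = kind,
    records_read = nrow(raw),
    records_normalized = records_normalized,
    pairs_in_source = length(unique(native_keys)),
    pairs_mapped = length(unique(mapped_keys)),
    rejects = if (length(rejects) > 0) do.call(rbind, rejects) else
      empty_df(source_id = "character", record_ref = "character",
               reason = "character")
  ), class = "etl_report")
  store$etl_report <- rbind(store$etl_report, data.frame(
    source_id = kind, records_read = report$records_read,
    records_normalized = report$records_normalized,
    pairs_in_source = report$pairs_in_source,
    pairs_mapped = report$pairs_mapped))
  store$etl_reject <- rbind(store$etl_reject, report$rejects)
  report
}

#' @export
print.etl_report <- function(x, ...) {
  p <- pct_one_decimal(x$pairs_mapped, x$pairs_in_source)
  cat("<etl_report> ", x$source_id, ": ", x$records_read, " read, ",
      x$records_normalized, " normalized, pairs ", x$pairs_mapped, "/",
      x$pairs_in_source, " (", p$display, "), ", nrow(x$rejects),
      " reject(s)\n", sep = "")
  invisible(x)
}
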