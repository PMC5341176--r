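# OMOP-style standard vocabulary store: concept lookup, "Maps to" translation,
# hierarchy traversal, and exact drug-name matching.

#' Construct a vocabulary store from in-memory tables
#'
#' The store mirrors an OMOP-style standard vocabulary: a `concepts` table with
#' one row per terminology entry, a `mappings` table of MAPS_TO rows pointing at
#' standard concepts, and an `ancestors` table holding the transitive (but not
#' reflexive) closure of the hierarchy. All referential and uniqueness
#' invariants are checked eagerly.
#'
#' @param concepts data frame with columns `concept_id`, `source_code`, `name`,
#'   `vocabulary_id`, `concept_class`, `is_standard`.
#' @param mappings data frame with columns `source_concept_id`,
#'   `target_concept_id`, `relationship` (always `"MAPS_TO"`).
#' @param ancestors data frame with columns `ancestor_concept_id`,
#'   `descendant_concept_id`.
#' @return An object of class `vocab_store`.
#' @export
vocabulary_store <- function(concepts, mappings = NULL, ancestors = NULL) {
  concepts <- as.data.frame(concepts)
  concepts$concept_id <- as.integer(concepts$concept_id)
  concepts$is_standard <- as.logical(concepts$is_standard)
  mappings <- if (is.null(mappings) || nrow(mappings) == 0) {
    empty_df(source_concept_id = "integer", target_concept_id = "integer",
             relationship = "character")
  } else {
    m <- as.data.frame(mappings)
    m$source_concept_id <- as.integer(m$source_concept_id)
    m$target_concept_id <- as.integer(m$target_concept_id)
    m
  }
  ancestors <- if (is.null(ancestors) || nrow(ancestors) == 0) {
    empty_df(ancestor_concept_id = "integer", descendant_concept_id = "integer")
  } else {
    a <- as.data.frame(ancestors)
    a$ancestor_concept_id <- as.integer(a$ancestor_concept_id)
    a$descendant_concept_id <- as.integer(a$descendant_concept_id)
    a
  }

  dup <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dup) > 0) {
    stop("duplicate concept_id in concept table: ", dup[1], call. = FALSE)
  }
  key <- paste(concepts$vocabulary_id, concepts$source_code, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- concepts[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (vocabulary_id, source_code): ", bad$vocabulary_id, "/",
         bad$source_code, call. = FALSE)
  }
  bad_vocab <- setdiff(unique(concepts$vocabulary_id), VOCABULARIES)
  if (length(bad_vocab) > 0) {
    stop("unknown vocabulary_id: ", bad_vocab[1], call. = FALSE)
  }
  drug_class <- concepts$concept_class %in% c("CLINICAL_DRUG", "INGREDIENT")
  if (any(drug_class & concepts$vocabulary_id != "RXNORM")) {
    stop("CLINICAL_DRUG/INGREDIENT concepts must be RXNORM", call. = FALSE)
  }
  std_ok <- !concepts$is_standard |
    (concepts$vocabulary_id == "RXNORM" & drug_class) |
    (concepts$vocabulary_id == "SNOMED" & concepts$concept_class == "CONDITION")
  if (!all(std_ok)) {
    bad <- concepts$concept_id[!std_ok][1]
    stop("concept ", bad, " flagged standard outside RXNORM drugs / SNOMED conditions",
         call. = FALSE)
  }

  check_ref <- function(ids, what) {
    missing <- setdiff(ids, concepts$concept_id)
    if (length(missing) > 0) {
      stop(what, " references unknown concept_id ", missing[1], call. = FALSE)
    }
  }
  check_ref(mappings$source_concept_id, "mapping")
  check_ref(mappings$target_concept_id, "mapping")
  check_ref(ancestors$ancestor_concept_id, "ancestor")
  check_ref(ancestors$descendant_concept_id, "ancestor")

  if (nrow(mappings) > 0) {
    tgt <- concepts$is_standard[match(mappings$target_concept_id, concepts$concept_id)]
    if (!all(tgt)) {
      stop("mapping target ", mappings$target_concept_id[!tgt][1],
           " is not a standard concept", call. = FALSE)
    }
    if (any(mappings$source_concept_id == mappings$target_concept_id)) {
      stop("self-mapping not allowed", call. = FALSE)
    }
    mk <- paste(mappings$source_concept_id, mappings$target_concept_id)
    if (anyDuplicated(mk)) {
      stop("duplicate mapping row: ", mk[duplicated(mk)][1], call. = FALSE)
    }
  }
  if (nrow(ancestors) > 0) {
    if (any(ancestors$ancestor_concept_id == ancestors$descendant_concept_id)) {
      stop("reflexive ancestor rows are not stored", call. = FALSE)
    }
    ak <- paste(ancestors$ancestor_concept_id, ancestors$descendant_concept_id)
    if (anyDuplicated(ak)) {
      stop("duplicate ancestor row: ", ak[duplicated(ak)][1], call. = FALSE)
    }
  }

  concepts$norm_name <- normalize_name(concepts$name)
  structure(
    list(concepts = concepts, mappings = mappings, ancestors = ancestors),
    class = "vocab_store"
  )
}

#' @export
print.vocab_store <- function(x, ...) {
  cat("<vocab_store> ", nrow(x$concepts), " concepts, ",
      nrow(x$mappings), " mappings, ", nrow(x$ancestors), " ancestor rows\n",
      sep = "")
  invisible(x)
}

#' Load a vocabulary from OMOP-download-dialect TSV files
#'
#' @param concept_path path to `CONCEPT.tsv`.
#' @param mapping_path path to `CONCEPT_RELATIONSHIP.tsv`.
#' @param ancestor_path path to `CONCEPT_ANCESTOR.tsv`.
#' @return A `vocab_store`.
#' @export
load_vocabulary <- function(concept_path, mapping_path, ancestor_path) {
  concepts <- read_tsv_file(concept_path)
  concepts$is_standard <- toupper(concepts$is_standard) == "TRUE"
  vocabulary_store(concepts, read_tsv_file(mapping_path), read_tsv_file(ancestor_path))
}

#' Write a vocabulary store back to its three TSV files
#'
#' Inverse of [load_vocabulary()]: loading the written files reproduces the
#' store field-for-field.
#' @param store a `vocab_store`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_vocabulary <- function(store, dir) {
  stopifnot(inherits(store, "vocab_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("concept_id", "source_code", "name", "vocabulary_id",
            "concept_class", "is_standard")
  write_tsv_file(store$concepts[, cols], file.path(dir, "CONCEPT.tsv"))
  write_tsv_file(store$mappings, file.path(dir, "CONCEPT_RELATIONSHIP.tsv"))
  write_tsv_file(store$ancestors, file.path(dir, "CONCEPT_ANCESTOR.tsv"))
  invisible(dir)
}

#' Look up one concept row by id
#' @param store a `vocab_store`.
#' @param concept_id integer concept id.
#' @return One-row data frame.
#' @export
get_concept <- function(store, concept_id) {
  i <- match(as.integer(concept_id), store$concepts$concept_id)
  if (is.na(i)) stop("unknown concept_id ", concept_id, call. = FALSE)
  store$concepts[i, , drop = FALSE]
}

has_concept <- function(store, concept_id) {
  as.integer(concept_id) %in% store$concepts$concept_id
}

concept_by_code <- function(store, vocabulary_id, source_code) {
  hit <- store$concepts[store$concepts$vocabulary_id == vocabulary_id &
                          store$concepts$source_code == source_code, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit
}

#' Translate a concept to its standard equivalents in a target vocabulary
#'
#' Follows MAPS_TO rows; a concept that is already standard in the target
#' vocabulary maps to itself. Fan-out is preserved: all targets are returned,
#' ascending by `concept_id`. An unmappable concept yields zero rows.
#'
#' @param store a `vocab_store`.
#' @param concept_id source concept id (must be loaded).
#' @param target_vocabulary `"RXNORM"` or `"SNOMED"` (any loaded vocabulary
#'   is accepted).
#' @return Data frame of concept rows (possibly empty).
#' @export
map_to_standard <- function(store, concept_id, target_vocabulary) {
  concept <- get_concept(store, concept_id)
  target_vocabulary <- match.arg(target_vocabulary, VOCABULARIES)
  if (concept$vocabulary_id == target_vocabulary && isTRUE(concept$is_standard)) {
    return(concept)
  }
  tgt_ids <- store$mappings$target_concept_id[
    store$mappings$source_concept_id == concept$concept_id]
  hits <- store$concepts[store$concepts$concept_id %in% tgt_ids &
                           store$concepts$vocabulary_id == target_vocabulary, ,
                         drop = FALSE]
  hits[order(hits$concept_id), , drop = FALSE]
}

#' Find the ingredient(s) above an RxNorm drug concept
#'
#' Walks `CONCEPT_ANCESTOR` to the INGREDIENT-class ancestors of a drug. An
#' ingredient returns itself (the stored closure is non-reflexive; the
#' reflexive case is added here). A clinical drug with no ingredient ancestor
#' yields zero rows.
#'
#' @param store a `vocab_store`.
#' @param drug_concept_id an RXNORM concept id.
#' @return Data frame of INGREDIENT concept rows, ascending `concept_id`.
#' @export
ingredient_for <- function(store, drug_concept_id) {
  concept <- get_concept(store, drug_concept_id)
  if (concept$vocabulary_id != "RXNORM") {
    stop("ingredient_for requires an RXNORM concept, got ",
         concept$vocabulary_id, call. = FALSE)
  }
  if (concept$concept_class == "INGREDIENT") {
    return(concept)
  }
  anc_ids <- store$ancestors$ancestor_concept_id[
    store$ancestors$descendant_concept_id == concept$concept_id]
  hits <- store$concepts[store$concepts$concept_id %in% anc_ids &
                           store$concepts$concept_class == "INGREDIENT", ,
                         drop = FALSE]
  hits[order(hits$concept_id), , drop = FALSE]
}

DEFAULT_SALT_SUFFIXES <- c(
  "sodium", "hydrochloride", "sulfate", "citrate", "tartrate", "maleate",
  "potassium", "calcium", "mesylate", "besylate"
)

# Name normalization pipeline: case-fold, trim, collapse internal whitespace,
# then optionally strip one trailing salt-form word.
normalize_name <- function(name, strip_salts = FALSE,
                           salt_suffixes = DEFAULT_SALT_SUFFIXES) {
  x <- tolower(trimws(name))
  x <- gsub("[[:space:]]+", " ", x)
  if (strip_salts) {
    pattern <- paste0(" (", paste(salt_suffixes, collapse = "|"), ")$")
    x <- sub(pattern, "", x)
  }
  x
}

#' Match RxNorm ingredients by exact normalized name
#'
#' The query is case-folded, trimmed, whitespace-collapsed, and (optionally)
#' stripped of a trailing salt-form suffix, then compared for exact equality
#' against similarly normalized ingredient names. No fuzzy matching.
#'
#' @param store a `vocab_store`.
#' @param name non-empty drug name string.
#' @param strip_salts strip a trailing salt suffix from the query
#'   (e.g. `"warfarin sodium"` matches `"warfarin"`)?
#' @param salt_suffixes character vector of suffix words to strip.
#' @return Data frame of matching RXNORM INGREDIENT rows, ascending
#'   `concept_id`; zero rows when nothing matches.
#' @export
match_drug_by_name <- function(store, name, strip_salts = FALSE,
                               salt_suffixes = DEFAULT_SALT_SUFFIXES) {
  if (!nzchar(trimws(name))) stop("name must be non-empty", call. = FALSE)
  q <- normalize_name(name, strip_salts = strip_salts, salt_suffixes = salt_suffixes)
  hits <- store$concepts[store$concepts$vocabulary_id == "RXNORM" &
                           store$concepts$concept_class == "INGREDIENT" &
                           store$concepts$norm_name == q, , drop = FALSE]
  hits[order(hits$concept_id), , drop = FALSE]
}
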