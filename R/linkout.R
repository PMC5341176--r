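# Evidence linkouts: the bridge between summary rows and drill-down
# annotations. Each (drug, HOI, source, evidence type) gets a canonical long
# URL plus a short base62 key from a persistent counter; both forms resolve to
# the exact annotation set recorded at mint time.

LINKOUT_SCHEME <- "laertes://evidence"

linkout_long_url <- function(drug_concept_id, hoi_concept_id, source_id,
                             evidence_type, annotation_type) {
  params <- c(atype = annotation_type, drug = as.character(drug_concept_id),
              hoi = as.character(hoi_concept_id), source = source_id,
              type = evidence_type)
  params <- params[order(names(params))]   # deterministic parameter order
  enc <- vapply(params, function(v) URLencode(v, reserved = TRUE), "")
  paste0(LINKOUT_SCHEME, "?", paste(names(params), enc, sep = "=", collapse = "&"))
}

#' Mint (or re-find) the linkout for one evidence record
#'
#' Deterministic: the long URL is a canonical sorted-parameter encoding of
#' (drug, HOI, source, evidence type, annotation type); the short key comes
#' from a persistent base62 counter, and re-encoding the same arguments
#' returns the existing key. The mapping rows tie the key to every annotation
#' matching the record's filters; minting with zero matching annotations is an
#' error (dangling linkouts are forbidden).
#'
#' @param store an `evidence_store`.
#' @param drug_concept_id drug concept at the source's native level.
#' @param hoi_concept_id standard SNOMED condition id.
#' @param source_id source key.
#' @param evidence_type evidence-type tag.
#' @return List of class `linkout`: `short_key`, `long_url`,
#'   `annotation_uids`.
#' @export
linkout_encode <- function(store, drug_concept_id, hoi_concept_id, source_id,
                           evidence_type) {
  ann_type <- KIND_REGISTRY[[source_id]]$annotation_type %||% ""
  long_url <- linkout_long_url(drug_concept_id, hoi_concept_id, source_id,
                               evidence_type, ann_type)
  existing <- store$linkout_map$short_key[store$linkout_map$long_url == long_url]
  if (length(existing) == 1) {
    uids <- sort(store$linkout_annotation$annotation_uid[
      store$linkout_annotation$short_key == existing])
    return(structure(list(short_key = existing, long_url = long_url,
                          annotation_uids = uids), class = "linkout"))
  }
  matches <- query_annotations(store, drug_concept_id = drug_concept_id,
                               hoi_concept_id = hoi_concept_id,
                               evidence_type = evidence_type)
  if (length(matches) == 0) {
    stop("refusing to mint a dangling linkout: no annotation matches drug ",
         drug_concept_id, ", hoi ", hoi_concept_id, ", type ", evidence_type,
         call. = FALSE)
  }
  uids <- sort(vapply(matches, function(a) a$annotation_uid, integer(1)))
  key <- base62_encode(store$next_linkout_counter)
  store$next_linkout_counter <- store$next_linkout_counter + 1L
  store$linkout_map <- rbind(store$linkout_map,
                             data.frame(short_key = key, long_url = long_url))
  store$linkout_annotation <- rbind(store$linkout_annotation,
                                    data.frame(short_key = key,
                                               annotation_uid = uids))
  structure(list(short_key = key, long_url = long_url, annotation_uids = uids),
            class = "linkout")
}

#' @export
print.linkout <- function(x, ...) {
  cat("<linkout ", x$short_key, "> ", x$long_url, " (",
      length(x$annotation_uids), " annotations)\n", sep = "")
  invisible(x)
}

#' Resolve a linkout (short key or long URL) to its annotations
#'
#' Returns exactly the annotations recorded at mint time, ordered by uid; the
#' short and long forms resolve identically.
#'
#' @param store an `evidence_store`.
#' @param key_or_url a short base62 key or a previously minted long URL.
#' @return List of `oa_annotation`.
#' @export
linkout_resolve <- function(store, key_or_url) {
  key <- if (startsWith(key_or_url, LINKOUT_SCHEME)) {
    hit <- store$linkout_map$short_key[store$linkout_map$long_url == key_or_url]
    if (length(hit) == 0) stop("unknown linkout URL: ", key_or_url, call. = FALSE)
    hit[1]
  } else {
    key_or_url
  }
  if (!key %in% store$linkout_map$short_key) {
    stop("unknown linkout key: ", key, call. = FALSE)
  }
  uids <- sort(store$linkout_annotation$annotation_uid[
    store$linkout_annotation$short_key == key])
  store$annotations[as.character(uids)]
}
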