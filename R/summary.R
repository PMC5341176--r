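# Relational summary store: per-source aggregated evidence records
# (drug_hoi_relationship / drug_hoi_evidence), four-level rollups
# (laertes_summary), coverage and overlap reports, and negative-control
# search.

relationship_id <- function(drug_concept_id, hoi_concept_id) {
  paste0(drug_concept_id, "-", hoi_concept_id)
}

upsert_relationship <- function(store, drug_concept_id, hoi_concept_id, vocab) {
  rid <- relationship_id(drug_concept_id, hoi_concept_id)
  if (!rid %in% store$drug_hoi_relationship$id) {
    store$drug_hoi_relationship <- rbind(store$drug_hoi_relationship, data.frame(
      id = rid,
      drug_concept_id = as.integer(drug_concept_id),
      rxnorm_drug = get_concept(vocab, drug_concept_id)$name,
      hoi_concept_id = as.integer(hoi_concept_id),
      snomed_hoi = get_concept(vocab, hoi_concept_id)$name))
  }
  rid
}

#' Aggregate one ETL run into evidence records with linkouts
#'
#' One evidence record per (drug, HOI, evidence type) from the source:
#' `RECORD_COUNT` records count the annotations behind the group,
#' `CASE_COUNT` records sum the source's case counts, and `PRR` records pass
#' the source value through unchanged (conflicting PRR values for one pair
#' are an aggregation error). Every record carries a freshly minted linkout.
#'
#' @param store an `evidence_store`.
#' @param pairs normalized-pair rows from one ETL run.
#' @param annotations the annotations loaded for those pairs.
#' @param source_id the source key.
#' @param vocab a `vocab_store` (for relationship display names).
#' @return The new `drug_hoi_evidence` rows, invisibly.
#' @export
aggregate_evidence <- function(store, pairs, annotations, source_id, vocab) {
  pairs <- as.data.frame(pairs)
  groups <- unique(pairs[, c("drug_concept_id", "hoi_concept_id",
                             "evidence_type", "statistic_type")])
  groups <- groups[order(groups$drug_concept_id, groups$hoi_concept_id,
                         groups$evidence_type), , drop = FALSE]
  new_rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- pairs$drug_concept_id == groups$drug_concept_id[g] &
      pairs$hoi_concept_id == groups$hoi_concept_id[g] &
      pairs$evidence_type == groups$evidence_type[g]
    grp <- pairs[sel, , drop = FALSE]
    stat_type <- groups$statistic_type[g]
    value <- switch(stat_type,
      RECORD_COUNT = {
        length(query_annotations(store,
                                 drug_concept_id = groups$drug_concept_id[g],
                                 hoi_concept_id = groups$hoi_concept_id[g],
                                 evidence_type = groups$evidence_type[g]))
      },
      CASE_COUNT = sum(grp$statistic_value),
      PRR = {
        vals <- unique(grp$statistic_value)
        if (length(vals) > 1) {
          stop("conflicting PRR values for pair ",
               relationship_id(groups$drug_concept_id[g], groups$hoi_concept_id[g]),
               " in source ", source_id, ": ",
               paste(vals, collapse = ", "), call. = FALSE)
        }
        vals
      }
    )
    rid <- upsert_relationship(store, groups$drug_concept_id[g],
                               groups$hoi_concept_id[g], vocab)
    lk <- linkout_encode(store, groups$drug_concept_id[g],
                         groups$hoi_concept_id[g], source_id,
                         groups$evidence_type[g])
    new_rows[[g]] <- data.frame(
      relationship_id = rid, source_id = source_id,
      evidence_type = groups$evidence_type[g],
      modality = unique(grp$modality)[1],
      statistic_type = stat_type, statistic_value = as.numeric(value),
      evidence_linkout = lk$long_url)
  }
  rows <- do.call(rbind, new_rows)
  key <- paste(rows$relationship_id, rows$source_id, rows$evidence_type,
               rows$statistic_type)
  if (anyDuplicated(key)) {
    stop("duplicate evidence record key: ", key[duplicated(key)][1], call. = FALSE)
  }
  store$drug_hoi_evidence <- rbind(store$drug_hoi_evidence, rows)
  invisible(rows)
}

# evidence rows annotated with ingredient/clinical-drug split (fan-out to all
# ingredients of a clinical drug); rows without an ingredient go to rejects.
evidence_at_ingredient_level <- function(store, vocab) {
  ev <- store$drug_hoi_evidence
  if (nrow(ev) == 0) {
    return(list(rows = NULL, rejects = empty_df(relationship_id = "character",
                                                reason = "character")))
  }
  rel <- store$drug_hoi_relationship
  ev <- merge(ev, rel, by.x = "relationship_id", by.y = "id", sort = FALSE)
  out <- list()
  rejects <- list()
  for (i in seq_len(nrow(ev))) {
    drug <- ev$drug_concept_id[i]
    concept <- get_concept(vocab, drug)
    is_cd <- concept$concept_class == "CLINICAL_DRUG"
    ings <- ingredient_for(vocab, drug)
    if (nrow(ings) == 0) {
      rejects[[length(rejects) + 1]] <- data.frame(
        relationship_id = ev$relationship_id[i], reason = "NO_INGREDIENT")
      next
    }
    out[[length(out) + 1]] <- data.frame(
      ingredient_concept_id = ings$concept_id,
      clinical_drug_concept_id = if (is_cd) drug else NA_integer_,
      hoi_concept_id = ev$hoi_concept_id[i],
      evidence_type = ev$evidence_type[i],
      statistic_type = ev$statistic_type[i],
      statistic_value = ev$statistic_value[i],
      source_id = ev$source_id[i])
  }
  list(rows = if (length(out) > 0) do.call(rbind, out) else NULL,
       rejects = if (length(rejects) > 0) do.call(rbind, rejects) else
         empty_df(relationship_id = "character", reason = "character"))
}

#' Build the four-level rollup summary
#'
#' Clinical-drug-level evidence is attributed to its ingredient(s) before
#' grouping; the four granularities are (1) ingredient, (2) ingredient + HOI,
#' (3) ingredient + clinical drug, (4) full detail. `RECORD_COUNT` and
#' `CASE_COUNT` aggregate by sum; `PRR` is a ratio and is carried only at
#' level 4, never summed. Evidence whose drug has no ingredient is routed to
#' a reject report (attribute `"rejects"`), not silently dropped.
#'
#' @param store an `evidence_store`.
#' @param vocab a `vocab_store`.
#' @return The `laertes_summary` data frame (also written into the store),
#'   with the reject report attached as attribute `rejects`.
#' @export
build_rollups <- function(store, vocab) {
  lev <- evidence_at_ingredient_level(store, vocab)
  if (is.null(lev$rows)) {
    store$laertes_summary <- evidence_store()$laertes_summary
    out <- store$laertes_summary
    attr(out, "rejects") <- lev$rejects
    return(out)
  }
  rows <- lev$rows
  counts <- rows[rows$statistic_type %in% c("RECORD_COUNT", "CASE_COUNT"), , drop = FALSE]

  roll <- function(df, level, by) {
    if (nrow(df) == 0) return(NULL)
    agg <- stats::aggregate(df$statistic_value,
                            by = lapply(by, function(col) df[[col]]),
                            FUN = sum)
    names(agg) <- c(by, "aggregate_value")
    data.frame(
      rollup_level = level,
      ingredient_concept_id = agg$ingredient_concept_id,
      clinical_drug_concept_id = if ("clinical_drug_concept_id" %in% by)
        agg$clinical_drug_concept_id else NA_integer_,
      hoi_concept_id = if ("hoi_concept_id" %in% by) agg$hoi_concept_id else NA_integer_,
      evidence_type = agg$evidence_type,
      statistic_type = agg$statistic_type,
      aggregate_value = agg$aggregate_value)
  }
  # aggregate() drops NA grouping levels; encode clinical drug NA as 0 and
  # restore afterwards so ingredient-level rows survive level-3/4 grouping
  counts2 <- counts
  counts2$clinical_drug_concept_id[is.na(counts2$clinical_drug_concept_id)] <- 0L
  rows2 <- rows
  rows2$clinical_drug_concept_id[is.na(rows2$clinical_drug_concept_id)] <- 0L

  l1 <- roll(counts, 1L, c("ingredient_concept_id", "evidence_type", "statistic_type"))
  l2 <- roll(counts, 2L, c("ingredient_concept_id", "hoi_concept_id",
                           "evidence_type", "statistic_type"))
  l3 <- roll(counts2, 3L, c("ingredient_concept_id", "clinical_drug_concept_id",
                            "evidence_type", "statistic_type"))
  l4 <- roll(rows2, 4L, c("ingredient_concept_id", "clinical_drug_concept_id",
                          "hoi_concept_id", "evidence_type", "statistic_type"))
  summary_df <- rbind(l1, l2, l3, l4)
  summary_df$clinical_drug_concept_id[summary_df$clinical_drug_concept_id %in% 0L] <- NA_integer_
  summary_df <- summary_df[order(summary_df$rollup_level,
                                 summary_df$ingredient_concept_id,
                                 summary_df$clinical_drug_concept_id,
                                 summary_df$hoi_concept_id,
                                 summary_df$evidence_type,
                                 summary_df$statistic_type), , drop = FALSE]
  rownames(summary_df) <- NULL
  store$laertes_summary <- summary_df
  attr(summary_df, "rejects") <- lev$rejects
  summary_df
}

#' Coverage report across ETL runs
#'
#' One row per source: distinct native pairs in the source, distinct pairs
#' surviving normalization, and the percentage at one decimal (round-half-
#' even). A zero-pair source renders as an em dash (undefined), never 0.
#'
#' @param etl_reports a list of `etl_report` objects, or an `evidence_store`
#'   (its recorded reports are used).
#' @return Data frame: `source_id`, `pairs_in_source`, `pairs_mapped`, `pct`
#'   (numeric, `NA` when undefined), `pct_display`.
#' @export
coverage_report <- function(etl_reports) {
  df <- if (inherits(etl_reports, "evidence_store")) {
    etl_reports$etl_report
  } else {
    do.call(rbind, lapply(etl_reports, function(r) data.frame(
      source_id = r$source_id, records_read = r$records_read,
      records_normalized = r$records_normalized,
      pairs_in_source = r$pairs_in_source, pairs_mapped = r$pairs_mapped)))
  }
  if (is.null(df) || nrow(df) == 0) stop("no ETL reports available", call. = FALSE)
  pct <- lapply(seq_len(nrow(df)), function(i)
    pct_one_decimal(df$pairs_mapped[i], df$pairs_in_source[i]))
  data.frame(source_id = df$source_id,
             pairs_in_source = df$pairs_in_source,
             pairs_mapped = df$pairs_mapped,
             pct = vapply(pct, function(p) p$pct, numeric(1)),
             pct_display = vapply(pct, function(p) p$display, ""))
}

# distinct (ingredient, hoi) pair keys for a set of sources
ingredient_pair_set <- function(store, vocab, source_ids) {
  lev <- evidence_at_ingredient_level(store, vocab)
  if (is.null(lev$rows)) return(character(0))
  rows <- lev$rows[lev$rows$source_id %in% source_ids, , drop = FALSE]
  unique(paste(rows$ingredient_concept_id, rows$hoi_concept_id))
}

#' Overlap of distinct drug-HOI pairs between source groups
#'
#' Compares distinct (ingredient, HOI) pair sets — after rolling drugs up to
#' ingredient level — between named, disjoint groups of sources. For every
#' group pair, and for all groups together, reports the union size `n`, the
#' intersection size, and `100 * intersection / union` at one decimal.
#'
#' @param store an `evidence_store`.
#' @param groups named list of source-id character vectors (disjoint,
#'   covering at least two sources).
#' @param vocab a `vocab_store`.
#' @return Data frame: `comparison`, `n_union`, `n_intersection`, `pct`,
#'   `pct_display`.
#' @export
overlap_report <- function(store, groups, vocab) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) {
    stop("groups must be disjoint; duplicated source: ",
         all_ids[duplicated(all_ids)][1], call. = FALSE)
  }
  sets <- lapply(groups, function(ids) ingredient_pair_set(store, vocab, ids))
  combos <- utils::combn(names(groups), 2, simplify = FALSE)
  if (length(groups) > 2) combos <- c(combos, list(names(groups)))
  rows <- lapply(combos, function(nm) {
    gs <- sets[nm]
    u <- unique(unlist(gs))
    inter <- Reduce(intersect, gs)
    p <- pct_one_decimal(length(inter), length(u))
    data.frame(comparison = paste(nm, collapse = " vs "),
               n_union = length(u), n_intersection = length(inter),
               pct = p$pct, pct_display = p$display)
  })
  do.call(rbind, rows)
}

#' Search for negative-control drug-HOI pairs
#'
#' Returns the candidate cross-product pairs with zero evidence records in
#' any loaded source at the ingredient rollup level — the pairs usable as
#' negative controls for calibrating observational estimates.
#'
#' @param store an `evidence_store`.
#' @param vocab a `vocab_store`.
#' @param drug_ids candidate RxNorm ingredient ids (nonempty; must be loaded
#'   concepts).
#' @param hoi_ids candidate SNOMED condition ids (nonempty; must be loaded).
#' @return Data frame `(ingredient_concept_id, hoi_concept_id)`, sorted.
#' @export
find_negative_controls <- function(store, vocab, drug_ids, hoi_ids) {
  stopifnot(length(drug_ids) >= 1, length(hoi_ids) >= 1)
  for (id in c(drug_ids, hoi_ids)) get_concept(vocab, id)  # lookup error if unknown
  evidence_keys <- ingredient_pair_set(store, vocab,
                                       unique(store$drug_hoi_evidence$source_id))
  grid <- expand.grid(ingredient_concept_id = sort(as.integer(drug_ids)),
                      hoi_concept_id = sort(as.integer(hoi_ids)))
  key <- paste(grid$ingredient_concept_id, grid$hoi_concept_id)
  out <- grid[!key %in% evidence_keys, , drop = FALSE]
  out <- out[order(out$ingredient_concept_id, out$hoi_concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
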