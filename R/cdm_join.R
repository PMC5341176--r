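# Join of the evidence base against CDM-shaped patient data: count distinct
# patients whose condition era starts within a window after a drug era start,
# restricted to drug-HOI pairs with evidence of stated types.

#' Read CDM-shaped drug/condition era tables
#'
#' @param dir directory holding `drug_era.tsv` and `condition_era.tsv`
#'   (ISO-8601 dates).
#' @return List with data frames `drug_era` and `condition_era` (`Date`
#'   columns).
#' @export
read_cdm <- function(dir) {
  de <- read_tsv_file(file.path(dir, "drug_era.tsv"))
  ce <- read_tsv_file(file.path(dir, "condition_era.tsv"))
  de$person_id <- as.integer(de$person_id)
  de$drug_concept_id <- as.integer(de$drug_concept_id)
  de$drug_era_start_date <- as.Date(de$drug_era_start_date)
  de$drug_era_end_date <- as.Date(de$drug_era_end_date)
  ce$person_id <- as.integer(ce$person_id)
  ce$condition_concept_id <- as.integer(ce$condition_concept_id)
  ce$condition_era_start_date <- as.Date(ce$condition_era_start_date)
  list(drug_era = de, condition_era = ce)
}

#' Count exposed cases for evidence-backed drug-HOI pairs
#'
#' Joins drug and condition eras on person, keeps pairs where the condition
#' era starts strictly after the drug era start and within `window_days`
#' calendar days of it, matches on exact concept ids against
#' `drug_hoi_relationship` (no ingredient expansion of CDM exposures), and
#' restricts to evidence records of the requested types. Patients are counted
#' once per output row (`count(distinct person_id)`).
#'
#' @param cdm list with `drug_era` and `condition_era` (see [read_cdm()]).
#' @param store an `evidence_store` with loaded evidence.
#' @param evidence_types nonempty character vector of evidence-type tags.
#' @param window_days window length in days (default 30).
#' @return Data frame `rxnorm_drug`, `snomed_hoi`, `evidence_type`,
#'   `evidence_linkout`, `pcount`, sorted by `pcount` descending then the
#'   three name columns ascending.
#' @export
count_exposed_cases <- function(cdm, store, evidence_types, window_days = 30) {
  stopifnot(length(evidence_types) >= 1, window_days >= 1)
  bad <- setdiff(evidence_types, known_evidence_types())
  if (length(bad) > 0) {
    stop("unknown evidence_type ", paste(bad, collapse = ", "),
         "; valid tags: ", paste(known_evidence_types(), collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(rxnorm_drug = character(0), snomed_hoi = character(0),
                      evidence_type = character(0),
                      evidence_linkout = character(0), pcount = integer(0))
  ev <- store$drug_hoi_evidence
  ev <- ev[ev$evidence_type %in% evidence_types, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  ev <- merge(ev, store$drug_hoi_relationship, by.x = "relationship_id",
              by.y = "id", sort = FALSE)

  eras <- merge(cdm$drug_era, cdm$condition_era, by = "person_id", sort = FALSE)
  dd <- as.integer(eras$condition_era_start_date - eras$drug_era_start_date)
  eras <- eras[dd > 0 & dd <= window_days, , drop = FALSE]
  if (nrow(eras) == 0) return(empty)

  joined <- merge(eras, ev,
                  by.x = c("drug_concept_id", "condition_concept_id"),
                  by.y = c("drug_concept_id", "hoi_concept_id"), sort = FALSE)
  if (nrow(joined) == 0) return(empty)
  agg <- joined %>%
    group_by(.data$rxnorm_drug, .data$snomed_hoi, .data$evidence_type,
             .data$evidence_linkout) %>%
    summarise(pcount = n_distinct(.data$person_id), .groups = "drop") %>%
    as.data.frame()
  agg <- agg[order(-agg$pcount, agg$rxnorm_drug, agg$snomed_hoi,
                   agg$evidence_type), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
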