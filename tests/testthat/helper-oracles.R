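# Independent oracle for the exposed-case count: a literal nested loop over
# (person, drug era, condition era), kept free of the package's join code.
brute_force_cases <- function(cdm, store, evidence_types, window_days = 30) {
  ev <- merge(store$drug_hoi_evidence, store$drug_hoi_relationship,
              by.x = "relationship_id", by.y = "id")
  ev <- ev[ev$evidence_type %in% evidence_types, ]
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    persons <- integer(0)
    for (p in unique(cdm$drug_era$person_id)) {
      de <- cdm$drug_era[cdm$drug_era$person_id == p &
                           cdm$drug_era$drug_concept_id == ev$drug_concept_id[i], ]
      ce <- cdm$condition_era[cdm$condition_era$person_id == p &
                                cdm$condition_era$condition_concept_id == ev$hoi_concept_id[i], ]
      hit <- FALSE
      for (a in seq_len(nrow(de))) for (b in seq_len(nrow(ce))) {
        dd <- as.integer(ce$condition_era_start_date[b] - de$drug_era_start_date[a])
        if (dd > 0 && dd <= window_days) hit <- TRUE
      }
      if (hit) persons <- c(persons, p)
    }
    if (length(persons) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        rxnorm_drug = ev$rxnorm_drug[i], snomed_hoi = ev$snomed_hoi[i],
        evidence_type = ev$evidence_type[i],
        evidence_linkout = ev$evidence_linkout[i],
        pcount = length(unique(persons)))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$pcount, out$rxnorm_drug, out$snomed_hoi,
                   out$evidence_type), ]
  rownames(out) <- NULL
  out
}
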