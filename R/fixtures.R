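# Seeded fixture generators: a miniature standard vocabulary, raw evidence
# files in all six source shapes, and CDM-shaped patient data with planted
# drug-HOI signals. Every generator is a pure function of (parameters, seed)
# and returns a ground-truth manifest fragment for oracle tests.

SPL_SECTIONS <- c("ADVERSE REACTIONS", "WARNINGS AND PRECAUTIONS", "BOXED WARNING")

# Well-known planted concepts (smallest ids in their ranges so that the
# highest-id generated ingredient/condition can be reserved as negative
# controls without touching them).
PLANTED_INGREDIENT_ID <- 1539403L   # "simvastatin"
PLANTED_CLINICAL_DRUG_ID <- 1539411L # "Simvastatin 20 MG Oral Tablet"
PLANTED_CONDITION_ID <- 45619309L   # "Rhabdomyolysis"

#' Generate a miniature standard vocabulary
#'
#' Emits, per ingredient: one RxNorm INGREDIENT, `drugs_per_ingredient`
#' CLINICAL_DRUG concepts with ancestor rows to the ingredient, and one MeSH
#' drug synonym with a MAPS_TO row. Per condition: one standard SNOMED
#' CONDITION plus one MedDRA and one MeSH synonym, each with a MAPS_TO row.
#' When at least two conditions exist, one SNOMED is-a ancestor row links the
#' first condition (parent) to the second (child) for hierarchy tests.
#'
#' The first ingredient, its first clinical drug, and the first condition are
#' fixed (simvastatin / Simvastatin 20 MG Oral Tablet / Rhabdomyolysis) so that
#' drill-down examples are stable across seeds; all other names are drawn from
#' the seeded RNG. The highest-id ingredient and condition are treated as
#' reserved negative-control concepts by [generate_source()].
#'
#' @param n_ingredients,drugs_per_ingredient,n_conditions counts, all >= 1.
#' @param seed integer RNG seed.
#' @param dir optional directory; when given, `CONCEPT.tsv`,
#'   `CONCEPT_RELATIONSHIP.tsv` and `CONCEPT_ANCESTOR.tsv` are written there.
#' @return List with elements `store` (a `vocab_store`) and `manifest`
#'   (inventory of generated ids, including the reserved negative-control ids).
#' @export
generate_vocabulary <- function(n_ingredients, drugs_per_ingredient, n_conditions,
                                seed, dir = NULL) {
  stopifnot(n_ingredients >= 1, drugs_per_ingredient >= 1, n_conditions >= 1)
  with_seed(seed, {
    ing_names <- c("simvastatin",
                   if (n_ingredients > 1)
                     vapply(seq_len(n_ingredients - 1), function(i) random_word(3), ""))
    cond_stems <- if (n_conditions > 1) {
      vapply(seq_len(n_conditions - 1), function(i) random_word(2), "")
    } else {
      character(0)
    }
    cond_suffix <- if (n_conditions > 1) {
      sample(c("itis", "osis", "emia", "algia", "opathy"), n_conditions - 1,
             replace = TRUE)
    } else {
      character(0)
    }
    cond_names <- c("Rhabdomyolysis", paste0(toupper(substr(cond_stems, 1, 1)),
                                             substr(cond_stems, 2, nchar(cond_stems)),
                                             cond_suffix))
    strengths <- sample(c(5L, 10L, 20L, 25L, 40L, 50L, 100L),
                        n_ingredients * drugs_per_ingredient, replace = TRUE)

    ing_ids <- c(PLANTED_INGREDIENT_ID,
                 if (n_ingredients > 1) 2000000L + seq_len(n_ingredients - 1))
    cond_ids <- c(PLANTED_CONDITION_ID,
                  if (n_conditions > 1) 46000000L + seq_len(n_conditions - 1))

    concepts <- list()
    mappings <- list()
    ancestors <- list()
    drugs <- list()

    for (i in seq_len(n_ingredients)) {
      concepts[[length(concepts) + 1]] <- data.frame(
        concept_id = ing_ids[i], source_code = as.character(200000L + i),
        name = ing_names[i], vocabulary_id = "RXNORM",
        concept_class = "INGREDIENT", is_standard = TRUE)
      # MeSH drug synonym mapped to the ingredient
      concepts[[length(concepts) + 1]] <- data.frame(
        concept_id = 44000000L + i, source_code = sprintf("D%06d", 100L + i),
        name = ing_names[i], vocabulary_id = "MESH",
        concept_class = "OTHER", is_standard = FALSE)
      mappings[[length(mappings) + 1]] <- data.frame(
        source_concept_id = 44000000L + i, target_concept_id = ing_ids[i],
        relationship = "MAPS_TO")
      for (j in seq_len(drugs_per_ingredient)) {
        drug_id <- if (i == 1L && j == 1L) {
          PLANTED_CLINICAL_DRUG_ID
        } else {
          2100000L + i * 1000L + j
        }
        strength <- if (i == 1L && j == 1L) 20L else strengths[(i - 1) * drugs_per_ingredient + j]
        drug_name <- paste0(toupper(substr(ing_names[i], 1, 1)),
                            substr(ing_names[i], 2, nchar(ing_names[i])),
                            " ", strength, " MG Oral Tablet")
        concepts[[length(concepts) + 1]] <- data.frame(
          concept_id = drug_id, source_code = as.character(310000L + i * 10L + j),
          name = drug_name, vocabulary_id = "RXNORM",
          concept_class = "CLINICAL_DRUG", is_standard = TRUE)
        ancestors[[length(ancestors) + 1]] <- data.frame(
          ancestor_concept_id = ing_ids[i], descendant_concept_id = drug_id)
        drugs[[length(drugs) + 1]] <- data.frame(
          concept_id = drug_id, ingredient_concept_id = ing_ids[i])
      }
    }

    for (k in seq_len(n_conditions)) {
      concepts[[length(concepts) + 1]] <- data.frame(
        concept_id = cond_ids[k], source_code = as.character(190000000L + k * 7L),
        name = cond_names[k], vocabulary_id = "SNOMED",
        concept_class = "CONDITION", is_standard = TRUE)
      concepts[[length(concepts) + 1]] <- data.frame(
        concept_id = 35000000L + k, source_code = as.character(10000000L + k),
        name = cond_names[k], vocabulary_id = "MEDDRA",
        concept_class = "CONDITION", is_standard = FALSE)
      concepts[[length(concepts) + 1]] <- data.frame(
        concept_id = 44500000L + k, source_code = sprintf("D%06d", 500L + k),
        name = cond_names[k], vocabulary_id = "MESH",
        concept_class = "OTHER", is_standard = FALSE)
      mappings[[length(mappings) + 1]] <- data.frame(
        source_concept_id = 35000000L + k, target_concept_id = cond_ids[k],
        relationship = "MAPS_TO")
      mappings[[length(mappings) + 1]] <- data.frame(
        source_concept_id = 44500000L + k, target_concept_id = cond_ids[k],
        relationship = "MAPS_TO")
    }
    # small SNOMED is-a chain: first condition is the parent of the second
    if (n_conditions >= 2) {
      ancestors[[length(ancestors) + 1]] <- data.frame(
        ancestor_concept_id = cond_ids[1], descendant_concept_id = cond_ids[2])
    }

    store <- vocabulary_store(do.call(rbind, concepts), do.call(rbind, mappings),
                              do.call(rbind, ancestors))
    manifest <- list(
      ingredients = data.frame(concept_id = ing_ids, name = ing_names),
      clinical_drugs = do.call(rbind, drugs),
      conditions = data.frame(concept_id = cond_ids, name = cond_names),
      reserved_ingredient_id = max(ing_ids),
      reserved_condition_id = max(cond_ids)
    )
    if (!is.null(dir)) write_vocabulary(store, dir)
    list(store = store, manifest = manifest)
  })
}

# ---- source-shape helpers ------------------------------------------------

usable_ingredients <- function(vocab) {
  ing <- vocab$concepts[vocab$concepts$concept_class == "INGREDIENT", ]
  ing <- ing[order(ing$concept_id), ]
  if (nrow(ing) > 1) ing[-nrow(ing), ] else ing  # drop reserved (highest id)
}

usable_conditions <- function(vocab) {
  cond <- vocab$concepts[vocab$concepts$vocabulary_id == "SNOMED" &
                           vocab$concepts$concept_class == "CONDITION", ]
  cond <- cond[order(cond$concept_id), ]
  if (nrow(cond) > 1) cond[-nrow(cond), ] else cond
}

# native synonym codes, recovered through the mapping table
synonym_code_for <- function(vocab, standard_id, synonym_vocab) {
  src <- vocab$mappings$source_concept_id[
    vocab$mappings$target_concept_id == standard_id]
  hit <- vocab$concepts[vocab$concepts$concept_id %in% src &
                          vocab$concepts$vocabulary_id == synonym_vocab, ]
  if (nrow(hit) == 0) {
    stop("no ", synonym_vocab, " synonym for concept ", standard_id, call. = FALSE)
  }
  hit$source_code[1]
}

cui_for <- function(concept_id) sprintf("C%07d", as.integer(concept_id) %% 10000000L)

#' List the reserved negative-control pairs of a fixture vocabulary
#'
#' [generate_source()] never samples the highest-id ingredient or the
#' highest-id SNOMED condition, so every pair involving either is guaranteed
#' absent from all generated sources.
#'
#' @param vocab a fixture `vocab_store`.
#' @return Data frame `(ingredient_concept_id, hoi_concept_id)`.
#' @export
reserved_negative_pairs <- function(vocab) {
  ing <- vocab$concepts[vocab$concepts$concept_class == "INGREDIENT", ]
  cond <- vocab$concepts[vocab$concepts$vocabulary_id == "SNOMED" &
                           vocab$concepts$concept_class == "CONDITION", ]
  res_ing <- max(ing$concept_id)
  res_cond <- max(cond$concept_id)
  out <- rbind(
    data.frame(ingredient_concept_id = res_ing,
               hoi_concept_id = sort(cond$concept_id)),
    data.frame(ingredient_concept_id = sort(ing$concept_id),
               hoi_concept_id = res_cond)
  )
  unique(out[order(out$ingredient_concept_id, out$hoi_concept_id), ])
}

#' Generate one raw evidence source file
#'
#' Produces `n_records` records in the kind-specific tab-delimited shape.
#' Mappable records sample distinct native (drug, HOI) pairs from the
#' vocabulary; exactly `round(n_records * unmappable_fraction)` records carry a
#' syntactically valid but unregistered drug code (or unknown drug name for
#' `EU_SPC`), exercising the mapping-miss path. `SPL_US` codes drugs at the
#' clinical-drug level; all other kinds at the ingredient level.
#' `MEDLINE_SEMMED` additionally writes a `UMLS_CROSSWALK.tsv` (cui,
#' concept_id) beside the source file.
#'
#' @param kind one of `SPL_US`, `EU_SPC`, `MEDLINE_MESH`, `MEDLINE_SEMMED`,
#'   `FAERS`, `CTD`.
#' @param vocab a fixture `vocab_store`.
#' @param n_records number of records to emit.
#' @param unmappable_fraction fraction in `[0, 1)` of deliberately unmappable
#'   records.
#' @param seed integer RNG seed.
#' @param dir output directory for the raw file.
#' @return List with `path`, `crosswalk_path` (SemMed only), and a manifest
#'   fragment: `planted_pairs` (ingredient, clinical drug, HOI, expected record
#'   count), `unmappable_records` (record references), `negative_pairs`.
#' @export
generate_source <- function(kind, vocab, n_records, unmappable_fraction, seed, dir) {
  kind <- match.arg(kind, SOURCE_KINDS)
  stopifnot(unmappable_fraction >= 0, unmappable_fraction < 1, n_records >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_unmap <- round(n_records * unmappable_fraction)
  n_map <- n_records - n_unmap

  ing <- usable_ingredients(vocab)
  cond <- usable_conditions(vocab)
  drugs <- if (kind == "SPL_US") {
    cd <- vocab$concepts[vocab$concepts$concept_class == "CLINICAL_DRUG", ]
    cd <- cd[order(cd$concept_id), ]
    # keep only drugs whose ingredient is usable
    keep <- vapply(cd$concept_id, function(id) {
      anc <- ingredient_for(vocab, id)
      nrow(anc) > 0 && all(anc$concept_id %in% ing$concept_id)
    }, logical(1))
    cd[keep, ]
  } else {
    ing
  }
  n_pairs_avail <- nrow(drugs) * nrow(cond)
  if (n_map > n_pairs_avail) {
    stop("cannot draw ", n_map, " distinct pairs from ", n_pairs_avail,
         " available combinations", call. = FALSE)
  }

  with_seed(seed, {
    pair_idx <- sample.int(n_pairs_avail, n_map)
    di <- ((pair_idx - 1) %% nrow(drugs)) + 1
    ci <- ((pair_idx - 1) %/% nrow(drugs)) + 1
    drug_rows <- drugs[di, , drop = FALSE]
    cond_rows <- cond[ci, , drop = FALSE]

    mappable <- rep(c(TRUE, FALSE), c(n_map, n_unmap))
    ord <- sample.int(n_records)
    mappable <- mappable[ord]
    # mapped-record index for each output row (NA for unmappable rows)
    map_slot <- cumsum(mappable) * ifelse(mappable, 1, NA)

    meddra_of <- function(k) synonym_code_for(vocab, cond_rows$concept_id[k], "MEDDRA")
    mesh_cond_of <- function(k) synonym_code_for(vocab, cond_rows$concept_id[k], "MESH")
    mesh_drug_of <- function(k) synonym_code_for(vocab, drug_rows$concept_id[k], "MESH")

    fake_code <- function(i) as.character(999000L + i)
    rows <- vector("list", n_records)
    unmap_refs <- character(0)
    unmap_seq <- 0L
    faers_stats <- NULL

    for (r in seq_len(n_records)) {
      k <- map_slot[r]
      if (!mappable[r]) unmap_seq <- unmap_seq + 1L
      rows[[r]] <- switch(kind,
        SPL_US = {
          label_id <- sprintf("SPL%05d", r)
          data.frame(
            label_id = label_id,
            set_id = paste0("set-", sprintf("%05d", r)),
            section_name = sample(SPL_SECTIONS, 1),
            rxnorm_clinical_drug_code = if (mappable[r]) drug_rows$source_code[k] else fake_code(unmap_seq),
            meddra_hoi_code = if (mappable[r]) meddra_of(k) else synonym_code_for(vocab, cond$concept_id[sample.int(nrow(cond), 1)], "MEDDRA"),
            mention_text = if (mappable[r]) paste0("Reports of ", cond_rows$name[k], " were observed.") else "Reports of an unresolvable reaction."
          )
        },
        EU_SPC = {
          name <- if (mappable[r]) {
            base <- drug_rows$name[k]
            switch(sample.int(4, 1),
                   base,
                   paste0(toupper(substr(base, 1, 1)), substr(base, 2, nchar(base))),
                   toupper(base),
                   paste0(base, " sodium"))
          } else {
            paste0("unobtainium", unmap_seq)
          }
          data.frame(
            doc_id = sprintf("EU%05d", r),
            drug_name = name,
            meddra_hoi_code = if (mappable[r]) meddra_of(k) else synonym_code_for(vocab, cond$concept_id[sample.int(nrow(cond), 1)], "MEDDRA")
          )
        },
        MEDLINE_MESH = {
          data.frame(
            pmid = as.character(20000000L + r),
            mesh_drug_code = if (mappable[r]) mesh_drug_of(k) else sprintf("D9%05d", unmap_seq),
            mesh_hoi_code = if (mappable[r]) mesh_cond_of(k) else synonym_code_for(vocab, cond$concept_id[sample.int(nrow(cond), 1)], "MESH"),
            pub_type = sample(PUB_TYPES, 1),
            title_abstract_text = if (mappable[r]) paste0(drug_rows$name[k], " associated ", cond_rows$name[k], ": a report.") else "An unresolvable association."
          )
        },
        MEDLINE_SEMMED = {
          data.frame(
            pmid = as.character(21000000L + r),
            cui_drug = if (mappable[r]) cui_for(drug_rows$concept_id[k]) else sprintf("C99%05d", unmap_seq),
            cui_hoi = if (mappable[r]) cui_for(cond_rows$concept_id[k]) else cui_for(cond$concept_id[sample.int(nrow(cond), 1)]),
            sentence_span = paste0(sample(1:200, 1), "|", sample(201:400, 1)),
            pub_type = sample(PUB_TYPES, 1)
          )
        },
        FAERS = {
          data.frame(
            drug_code = if (mappable[r]) drug_rows$source_code[k] else fake_code(unmap_seq),
            hoi_code = if (mappable[r]) meddra_of(k) else synonym_code_for(vocab, cond$concept_id[sample.int(nrow(cond), 1)], "MEDDRA"),
            case_count = sample(1:50, 1),
            prr = round(exp(stats::rnorm(1, 0.5, 0.6)), 2)
          )
        },
        CTD = {
          data.frame(
            mesh_chemical_code = if (mappable[r]) mesh_drug_of(k) else sprintf("D9%05d", unmap_seq),
            mesh_disease_code = if (mappable[r]) mesh_cond_of(k) else synonym_code_for(vocab, cond$concept_id[sample.int(nrow(cond), 1)], "MESH")
          )
        }
      )
      if (!mappable[r]) {
        unmap_refs <- c(unmap_refs, record_ref(kind, rows[[r]], r))
      }
    }
    raw <- do.call(rbind, rows)
    path <- file.path(dir, paste0(kind, ".tsv"))
    write_tsv_file(raw, path)

    crosswalk_path <- NULL
    if (kind == "MEDLINE_SEMMED") {
      all_ing <- vocab$concepts[vocab$concepts$concept_class == "INGREDIENT", ]
      all_cond <- vocab$concepts[vocab$concepts$vocabulary_id == "SNOMED" &
                                   vocab$concepts$concept_class == "CONDITION", ]
      xwalk <- data.frame(
        cui = cui_for(c(all_ing$concept_id, all_cond$concept_id)),
        concept_id = c(all_ing$concept_id, all_cond$concept_id)
      )
      xwalk <- xwalk[order(xwalk$cui), ]
      crosswalk_path <- file.path(dir, "UMLS_CROSSWALK.tsv")
      write_tsv_file(xwalk, crosswalk_path)
    }

    planted <- if (n_map > 0) {
      ing_of <- vapply(drug_rows$concept_id, function(id) {
        anc <- ingredient_for(vocab, id)
        as.integer(anc$concept_id[1])
      }, integer(1))
      pp <- data.frame(
        ingredient_concept_id = ing_of,
        clinical_drug_concept_id = if (kind == "SPL_US") drug_rows$concept_id else NA_integer_,
        hoi_concept_id = cond_rows$concept_id,
        source_name = kind
      )
      pp %>%
        group_by(.data$ingredient_concept_id, .data$clinical_drug_concept_id,
                 .data$hoi_concept_id, .data$source_name) %>%
        summarise(expected_record_count = dplyr::n(), .groups = "drop") %>%
        as.data.frame()
    } else {
      data.frame(ingredient_concept_id = integer(0),
                 clinical_drug_concept_id = integer(0),
                 hoi_concept_id = integer(0), source_name = character(0),
                 expected_record_count = integer(0))
    }

    list(path = path, crosswalk_path = crosswalk_path,
         planted_pairs = planted, unmappable_records = unmap_refs,
         negative_pairs = reserved_negative_pairs(vocab),
         n_records = n_records)
  })
}

# stable record reference "<KIND>:<native id or row>"
record_ref <- function(kind, record, row) {
  id <- switch(kind,
    SPL_US = record$label_id, EU_SPC = record$doc_id,
    MEDLINE_MESH = record$pmid, MEDLINE_SEMMED = record$pmid,
    FAERS = paste0("row", row), CTD = paste0("row", row))
  paste0(kind, ":", id)
}

#' Generate CDM-shaped patient data with planted drug-HOI cases
#'
#' Each planted triple `(drug_concept_id, condition_concept_id, day_offset)`
#' creates one person with a drug era and a condition era starting
#' `day_offset` calendar days after the drug era start (negative and >30
#' offsets plant deliberate non-cases). Background persons receive random eras
#' whose offsets always fall outside `(0, 30]`, so the returned `cdm_truth`
#' lists exactly the qualifying persons under the 30-day rule.
#'
#' @param vocab a fixture `vocab_store`.
#' @param n_persons total persons (>= number of planted triples).
#' @param planted data frame with columns `drug_concept_id`,
#'   `condition_concept_id`, `day_offset`.
#' @param seed integer RNG seed.
#' @param dir output directory for `drug_era.tsv` / `condition_era.tsv`.
#' @return List with `drug_era`, `condition_era` (data frames with `Date`
#'   columns), file paths, and `cdm_truth` (drug, condition, person_id for
#'   planted offsets in `(0, 30]`).
#' @export
generate_cdm <- function(vocab, n_persons, planted, seed, dir) {
  planted <- as.data.frame(planted)
  stopifnot(n_persons >= nrow(planted))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ing <- vocab$concepts[vocab$concepts$concept_class == "INGREDIENT", ]
  cond <- vocab$concepts[vocab$concepts$vocabulary_id == "SNOMED" &
                           vocab$concepts$concept_class == "CONDITION", ]
  base <- as.Date("2019-01-01")
  with_seed(seed, {
    n_bg <- n_persons - nrow(planted)
    person_id <- seq_len(n_persons)
    drug_id <- c(as.integer(planted$drug_concept_id),
                 sample(ing$concept_id, n_bg, replace = TRUE))
    cond_id <- c(as.integer(planted$condition_concept_id),
                 sample(cond$concept_id, n_bg, replace = TRUE))
    offset <- c(as.integer(planted$day_offset),
                sample(c(-30:0, 31:120), n_bg, replace = TRUE))
    start <- base + sample(0:364, n_persons, replace = TRUE)
    drug_era <- data.frame(
      person_id = person_id,
      drug_concept_id = drug_id,
      drug_era_start_date = start,
      drug_era_end_date = start + sample(7:90, n_persons, replace = TRUE)
    )
    condition_era <- data.frame(
      person_id = person_id,
      condition_concept_id = cond_id,
      condition_era_start_date = start + offset
    )
    truth <- data.frame(
      drug_concept_id = drug_era$drug_concept_id[seq_len(nrow(planted))],
      condition_concept_id = condition_era$condition_concept_id[seq_len(nrow(planted))],
      person_id = seq_len(nrow(planted))
    )[planted$day_offset > 0 & planted$day_offset <= 30, , drop = FALSE]

    de_path <- file.path(dir, "drug_era.tsv")
    ce_path <- file.path(dir, "condition_era.tsv")
    de_out <- drug_era
    de_out$drug_era_start_date <- format(de_out$drug_era_start_date)
    de_out$drug_era_end_date <- format(de_out$drug_era_end_date)
    ce_out <- condition_era
    ce_out$condition_era_start_date <- format(ce_out$condition_era_start_date)
    write_tsv_file(de_out, de_path)
    write_tsv_file(ce_out, ce_path)
    list(drug_era = drug_era, condition_era = condition_era,
         drug_era_path = de_path, condition_era_path = ce_path,
         cdm_truth = truth)
  })
}

#' Generate a complete fixture suite (vocabulary + all six sources)
#'
#' Convenience wrapper used by the command line and the acceptance pipeline:
#' one vocabulary plus one raw file per source kind, each with its own derived
#' seed, sharing reserved negative-control concepts.
#'
#' @param dir output directory.
#' @param seed master seed; per-source seeds are derived from it.
#' @param n_records records per source.
#' @param unmappable_fraction shared unmappable fraction.
#' @param n_ingredients,drugs_per_ingredient,n_conditions vocabulary size.
#' @return List with `vocab` (store), `vocab_manifest`, and per-kind source
#'   manifests under `sources`.
#' @export
generate_fixture_suite <- function(dir, seed, n_records = 40,
                                   unmappable_fraction = 0,
                                   n_ingredients = 8, drugs_per_ingredient = 2,
                                   n_conditions = 10) {
  vocab_dir <- file.path(dir, "vocab")
  gen <- generate_vocabulary(n_ingredients, drugs_per_ingredient, n_conditions,
                             seed = seed, dir = vocab_dir)
  src_dir <- file.path(dir, "sources")
  sources <- list()
  for (i in seq_along(SOURCE_KINDS)) {
    kind <- SOURCE_KINDS[i]
    sources[[kind]] <- generate_source(kind, gen$store, n_records,
                                       unmappable_fraction,
                                       seed = seed + i, dir = src_dir)
  }
  list(vocab = gen$store, vocab_manifest = gen$manifest,
       vocab_dir = vocab_dir, sources = sources)
}
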