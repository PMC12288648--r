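#' The eight therapy-sequence phenotype labels
#'
#' Encounters are classified by the type and order of respiratory-support
#' therapies received: a single therapy (IMV, NIPPV or HFNI "Only"), a
#' noninvasive therapy followed by intubation ("NIPPV Failure", "HFNI
#' Failure"), intubation followed by a noninvasive therapy ("IMV to NIPPV",
#' "IMV to HFNI"), or no qualifying therapy ("None").
#'
#' @return Character vector of the eight labels, in fixed order.
#' @export
phenotype_levels <- function() {
  c(
    "IMV Only", "NIPPV Only", "HFNI Only",
    "NIPPV Failure", "HFNI Failure",
    "IMV to NIPPV", "IMV to HFNI", "None"
  )
}

#' Parse recorded ages
#'
#' Ages are stored as strings because of the de-identification sentinel
#' `">89"`, which parses as 90. Anything else must be a whole number of
#' years; unparseable values return NA with a warning.
#'
#' @param age character (or numeric) vector of recorded ages.
#' @return Integer vector of years.
#' @export
parse_age <- function(age) {
  age <- trimws(as.character(age))
  out <- rep(NA_integer_, length(age))
  out[age == ">89"] <- 90L
  plain <- grepl("^[0-9]+$", age)
  out[plain] <- as.integer(age[plain])
  bad <- !plain & age != ">89" & !is.na(age)
  if (any(bad)) {
    warning(sum(bad), " unparseable age value(s); affected encounters excluded",
      call. = FALSE
    )
  }
  out
}

#' Cohort filters: first encounter per patient, adults only
#'
#' `select_first_encounters()` keeps, for each patient, the encounter with
#' the smallest admission order; duplicated (patient, order) pairs are an
#' ambiguity error. `filter_adults()` keeps encounters whose parsed age is at
#' least 18 (strictly-less-than-18 excluded; the `">89"` sentinel is always
#' kept; unparseable ages are excluded with a warning).
#'
#' @param encounters a tibble with columns `encounter_id`, `patient_id`,
#'   `age_years`, `admit_order`.
#' @return The filtered encounter tibble.
#' @export
select_first_encounters <- function(encounters) {
  dup <- encounters |>
    dplyr::count(.data$patient_id, .data$admit_order) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(
      paste0(
        "Ambiguous encounter ordering: duplicated (patient_id, admit_order) for ",
        nrow(dup), " pair(s), e.g. patient ", dup$patient_id[1]
      ),
      class = "resppheno_ambiguity_error"
    )
  }
  encounters |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$admit_order, n = 1) |>
    dplyr::ungroup()
}

#' @rdname select_first_encounters
#' @export
filter_adults <- function(encounters) {
  age <- parse_age(encounters$age_years)
  dplyr::filter(encounters, !is.na(age) & age >= 18)
}

# Core rule engine on parallel vectors of offsets and concept categories
# (categories from concept_category(); NA = irrelevant). Returns one of the
# eight labels or aborts with class "resppheno_unclassifiable".
label_from_events <- function(offset, category) {
  imv_off <- offset[!is.na(category) & category == "IMV"]
  n_med <- sum(!is.na(category) & category == "medication")
  ni <- !is.na(category) & (category == "NIPPV" | category == "HFNI")
  ni_off <- offset[ni]
  ni_cat <- category[ni]

  has_imv <- length(imv_off) >= 2 && n_med >= 1
  if (has_imv) {
    keep <- ni_off < min(imv_off) | ni_off > max(imv_off)
    ni_off <- ni_off[keep]
    ni_cat <- ni_cat[keep]
  }
  has_ni <- length(ni_off) >= 2
  if (!has_imv && !has_ni) {
    return("None")
  }
  ni_label <- if (has_ni && any(ni_cat == "HFNI")) "HFNI" else "NIPPV"
  if (has_imv && !has_ni) {
    return("IMV Only")
  }
  if (!has_imv) {
    return(paste(ni_label, "Only"))
  }
  imv_start <- min(imv_off)
  ni_start <- min(ni_off)
  if (ni_start == imv_start) {
    rlang::abort(
      "Unclassifiable encounter: IMV and noninvasive episodes start at the same offset",
      class = "resppheno_unclassifiable"
    )
  }
  if (ni_start < imv_start) paste(ni_label, "Failure") else paste("IMV to", ni_label)
}

#' Detect therapy episodes in one encounter
#'
#' Applies the therapy criteria to one encounter's records (already filtered
#' to the selected concepts): an IMV episode requires at least two records
#' whose concept indicates IMV plus at least one record whose concept is an
#' intubation-related medication; a noninvasive episode requires at least two
#' records whose concepts indicate NIPPV or HFNI, and is labeled HFNI when at
#' least one of them is an HFNI concept, NIPPV otherwise. Episode bounds are
#' the min/max offsets of the supporting therapy records (medication records
#' support the IMV criterion but do not extend its span).
#'
#' @param records record tibble for a single encounter.
#' @param lexicon a [relevance_lexicon()].
#' @return A tibble of episodes: `therapy`, `start_offset`, `end_offset`,
#'   `supporting_record_count` (zero rows when no criterion is met).
#' @export
detect_therapies <- function(records, lexicon) {
  built <- build_concepts(records)
  cat <- concept_category(built$concept, lexicon)
  off <- built$offset_minutes
  imv_off <- off[!is.na(cat) & cat == "IMV"]
  n_med <- sum(!is.na(cat) & cat == "medication")
  ni <- !is.na(cat) & (cat == "NIPPV" | cat == "HFNI")
  ni_off <- off[ni]
  ni_cat <- cat[ni]

  out <- tibble::tibble(
    therapy = character(), start_offset = integer(),
    end_offset = integer(), supporting_record_count = integer()
  )
  if (length(imv_off) >= 2 && n_med >= 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      therapy = "IMV",
      start_offset = min(imv_off), end_offset = max(imv_off),
      supporting_record_count = length(imv_off)
    ))
  }
  if (length(ni_off) >= 2) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      therapy = if (any(ni_cat == "HFNI")) "HFNI" else "NIPPV",
      start_offset = min(ni_off), end_offset = max(ni_off),
      supporting_record_count = length(ni_off)
    ))
  }
  out
}

#' Remove noninvasive records inside the IMV span
#'
#' When an encounter has a qualifying IMV episode, NIPPV and HFNI records
#' whose offsets fall inside the closed interval from the first to the last
#' IMV record are removed from consideration (they typically reflect weaning
#' trials during ventilation), and the noninvasive criteria are reassessed on
#' what remains. Without an IMV episode the records pass through unchanged.
#' The operation is idempotent.
#'
#' @inheritParams detect_therapies
#' @return The record tibble with in-span noninvasive records dropped.
#' @export
apply_imv_interval_rule <- function(records, lexicon) {
  built <- build_concepts(records)
  cat <- concept_category(built$concept, lexicon)
  imv_off <- built$offset_minutes[!is.na(cat) & cat == "IMV"]
  n_med <- sum(!is.na(cat) & cat == "medication")
  if (length(imv_off) < 2 || n_med < 1) {
    return(records)
  }
  lo <- min(imv_off)
  hi <- max(imv_off)
  is_ni <- !is.na(cat) & (cat == "NIPPV" | cat == "HFNI")
  drop <- is_ni & built$offset_minutes >= lo & built$offset_minutes <= hi
  records[!drop, , drop = FALSE]
}

#' Classify a set of therapy episodes into a phenotype
#'
#' No episodes is "None"; a single episode is "<therapy> Only"; a noninvasive
#' episode starting before the IMV episode is a failure phenotype ("NIPPV
#' Failure"/"HFNI Failure"); IMV starting first gives "IMV to NIPPV"/"IMV to
#' HFNI". Episode combinations outside the eight classes — two episodes with
#' equal start offsets, duplicate therapies, or more than two episodes — are
#' an explicit `resppheno_unclassifiable` error, never silently coerced.
#'
#' @param episodes an episode tibble as returned by [detect_therapies()].
#' @return A single phenotype label (see [phenotype_levels()]).
#' @export
classify_phenotype <- function(episodes) {
  n <- nrow(episodes)
  if (n == 0) {
    return("None")
  }
  if (n == 1) {
    return(paste(episodes$therapy, "Only"))
  }
  unclass_abort <- function(msg) {
    rlang::abort(paste0("Unclassifiable encounter: ", msg),
      class = "resppheno_unclassifiable"
    )
  }
  if (n > 2) unclass_abort("more than two therapy episodes")
  if (anyDuplicated(episodes$therapy) > 0) unclass_abort("duplicate therapy episodes")
  is_imv <- episodes$therapy == "IMV"
  if (sum(is_imv) != 1) unclass_abort("two concurrent noninvasive episodes")
  imv_start <- episodes$start_offset[is_imv]
  ni_start <- episodes$start_offset[!is_imv]
  ni_label <- episodes$therapy[!is_imv]
  if (ni_start == imv_start) {
    unclass_abort("IMV and noninvasive episodes start at the same offset")
  }
  if (ni_start < imv_start) paste(ni_label, "Failure") else paste("IMV to", ni_label)
}

#' Phenotype a single encounter's records
#'
#' Composes the per-encounter steps: filter records to the selected concepts,
#' apply the IMV interval rule, detect therapy episodes and classify. Records
#' whose concepts are in none of the lexicon's relevant sets (distractors or
#' unknown strings) never influence the label.
#'
#' @inheritParams detect_therapies
#' @return A single phenotype label.
#' @examples
#' lex <- default_lexicon()
#' bank <- default_concept_bank()
#' recs <- plant_phenotype("IMV Only", bank, encounter_id = "e1")
#' phenotype_encounter(recs, lex)
#' @export
phenotype_encounter <- function(records, lexicon) {
  built <- build_concepts(records)
  cat <- concept_category(built$concept, lexicon)
  label_from_events(built$offset_minutes, cat)
}

#' Phenotype a cohort with the reference rule-based algorithm
#'
#' Runs the full deterministic pipeline: keep each patient's first encounter,
#' drop under-18s, then phenotype each surviving encounter from its records
#' (encounters with no qualifying records are "None"). This is the algorithm
#' used both as ground truth for evaluation and as the reference the
#' model-backed stages are compared against.
#'
#' @param records record tibble for the whole cohort.
#' @param encounters encounter tibble (`encounter_id`, `patient_id`,
#'   `age_years`, `admit_order`).
#' @param lexicon a [relevance_lexicon()].
#' @return A tibble `encounter_id`, `phenotype` for the encounters surviving
#'   the cohort filters.
#' @export
reference_phenotypes <- function(records, encounters, lexicon) {
  kept <- encounters |>
    select_first_encounters() |>
    filter_adults()
  built <- build_concepts(records)
  built <- built[built$encounter_id %in% kept$encounter_id, , drop = FALSE]
  cat <- concept_category(built$concept, lexicon)
  rel <- !is.na(cat)
  off <- built$offset_minutes[rel]
  cat <- cat[rel]
  ids <- built$encounter_id[rel]
  labels <- vapply(
    split(seq_along(ids), ids),
    function(idx) label_from_events(off[idx], cat[idx]),
    character(1)
  )
  tibble::tibble(encounter_id = kept$encounter_id) |>
    dplyr::mutate(
      phenotype = dplyr::coalesce(unname(labels[.data$encounter_id]), "None")
    ) |>
    dplyr::arrange(.data$encounter_id)
}
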