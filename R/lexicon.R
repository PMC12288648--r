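#' Relevance lexicon for respiratory-support phenotyping
#'
#' The rule-based phenotyper and the oracle/noisy test backends decide
#' relevance by exact membership of a constructed-concept string in one of
#' five disjoint sets: concepts indicating IMV (invasive mechanical
#' ventilation), NIPPV (noninvasive positive pressure ventilation), HFNI
#' (high-flow nasal insufflation), intubation-related medications
#' (induction/paralytic/continuous-sedation agents), and distractors
#' (concepts relevant to none of the therapies).
#'
#' @param imv,nippv,hfni character vectors of constructed-concept strings
#'   indicating each therapy.
#' @param medications character vector of medication concept strings.
#' @param distractors character vector of concept strings relevant to nothing.
#' @return An object of class `relevance_lexicon`.
#' @seealso [default_lexicon()], [default_concept_bank()]
#' @export
relevance_lexicon <- function(imv, nippv, hfni, medications, distractors = character()) {
  lex <- structure(
    list(
      therapy = list(
        IMV = unique(as.character(imv)),
        NIPPV = unique(as.character(nippv)),
        HFNI = unique(as.character(hfni))
      ),
      medications = unique(as.character(medications)),
      distractors = unique(as.character(distractors))
    ),
    class = "relevance_lexicon"
  )
  sets <- c(lex$therapy, list(medications = lex$medications, distractors = lex$distractors))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
        rlang::abort(
          paste0(
            "Lexicon sets must be pairwise disjoint; '",
            names(sets)[i], "' and '", names(sets)[j], "' overlap."
          ),
          class = "resppheno_lexicon_error"
        )
      }
    }
  }
  lex
}

#' @export
print.relevance_lexicon <- function(x, ...) {
  cat("<relevance_lexicon>\n")
  cat("  IMV concepts:        ", length(x$therapy$IMV), "\n")
  cat("  NIPPV concepts:      ", length(x$therapy$NIPPV), "\n")
  cat("  HFNI concepts:       ", length(x$therapy$HFNI), "\n")
  cat("  medication concepts: ", length(x$medications), "\n")
  cat("  distractor concepts: ", length(x$distractors), "\n")
  invisible(x)
}

#' @rdname relevance_lexicon
#' @param lexicon a `relevance_lexicon`.
#' @export
relevant_concepts <- function(lexicon) {
  unique(c(unlist(lexicon$therapy, use.names = FALSE), lexicon$medications))
}

# category of each concept string: "IMV", "NIPPV", "HFNI", "medication" or NA
concept_category <- function(concepts, lexicon) {
  out <- rep(NA_character_, length(concepts))
  out[concepts %in% lexicon$therapy$IMV] <- "IMV"
  out[concepts %in% lexicon$therapy$NIPPV] <- "NIPPV"
  out[concepts %in% lexicon$therapy$HFNI] <- "HFNI"
  out[concepts %in% lexicon$medications] <- "medication"
  out
}

#' Default concept bank
#'
#' A small bank of realistic eICU-style table rows, one per concept the
#' default lexicon knows about, spanning all nine source tables: ~28 therapy
#' concepts (modeled on charting values such as "BiPAP/CPAP" for NIPPV and
#' "Hi Flow NC" for HFNI), 10 intubation-related medication concepts, and 40
#' distractors. The synthetic cohort generator samples rows from this bank to
#' materialise records, so generated data and lexicon are consistent by
#' construction. Fully overridable: supply your own bank with the same
#' columns.
#'
#' @return A tibble with the record field columns plus `category` (one of
#'   `"IMV"`, `"NIPPV"`, `"HFNI"`, `"medication"`, `"distractor"`) and
#'   `concept` (the constructed-concept text).
#' @export
default_concept_bank <- function() {
  e <- function(table, category, f1 = NULL, f2 = NULL, f3 = NULL) {
    flds <- source_tables()$fields[[match(table, source_table_names())]]
    vals <- c(f1, f2, f3)
    stopifnot(length(vals) == length(flds))
    row <- stats::setNames(as.list(vals), flds)
    c(list(table = table, category = category), row)
  }
  rows <- list(
    # --- IMV ---
    e("Nurse Charting", "IMV", "O2 Admin Device", "Ventilator"),
    e("Nurse Charting", "IMV", "O2 Admin Device", "ET Tube"),
    e("Respiratory Care", "IMV", "Oral ETT"),
    e("Respiratory Care", "IMV", "Nasal ETT"),
    e("Respiratory Care", "IMV", "Tracheostomy"),
    e("Treatment", "IMV", "pulmonary|ventilation and oxygenation|mechanical ventilation"),
    e("Treatment", "IMV", "pulmonary|ventilation and oxygenation|mechanical ventilation|assist controlled"),
    e("Care Plan General", "IMV", "Airway", "Intubated - oral ETT"),
    e("Note", "IMV", "airway", "oral ETT secured at 22 cm"),
    e("Respiratory Charting", "IMV", "respFlowSettings", "Vent Mode", "SIMV"),
    # --- NIPPV ---
    e("Nurse Charting", "NIPPV", "O2 Admin Device", "BiPAP/CPAP"),
    e("Nurse Charting", "NIPPV", "O2 Admin Device", "BiPAP"),
    e("Nurse Charting", "NIPPV", "O2 Admin Device", "CPAP"),
    e("Respiratory Charting", "NIPPV", "respFlowSettings", "NIV Mode", "BiPAP"),
    e("Respiratory Charting", "NIPPV", "respFlowSettings", "EPAP", "5"),
    e("Treatment", "NIPPV", "pulmonary|ventilation and oxygenation|non-invasive ventilation"),
    e("Treatment", "NIPPV", "pulmonary|ventilation and oxygenation|CPAP/PEEP therapy"),
    e("Care Plan General", "NIPPV", "Airway", "Not intubated - BiPAP"),
    e("Nurse Care", "NIPPV", "BiPAP mask fitted and checked"),
    e("Note", "NIPPV", "respiratory status", "tolerating BiPAP"),
    # --- HFNI ---
    e("Nurse Charting", "HFNI", "O2 Admin Device", "Hi Flow NC"),
    e("Nurse Charting", "HFNI", "O2 Admin Device", "High Flow NC"),
    e("Nurse Charting", "HFNI", "O2 Admin Device", "HFNC"),
    e("Respiratory Charting", "HFNI", "respFlowSettings", "HFNC Flow Rate", "40"),
    e("Treatment", "HFNI", "pulmonary|ventilation and oxygenation|high flow nasal cannula"),
    e("Care Plan General", "HFNI", "Airway", "Not intubated - high flow nasal cannula"),
    e("Nurse Care", "HFNI", "high flow nasal cannula in place"),
    e("Note", "HFNI", "respiratory status", "on heated high flow NC"),
    # --- intubation-related medications ---
    e("Medication", "medication", "SUCCINYLCHOLINE"),
    e("Medication", "medication", "ROCURONIUM BROMIDE"),
    e("Medication", "medication", "ETOMIDATE"),
    e("Medication", "medication", "KETAMINE HCL"),
    e("Medication", "medication", "VECURONIUM BROMIDE"),
    e("Medication", "medication", "CISATRACURIUM"),
    e("Infusion Drug", "medication", "Propofol (mcg/kg/min)"),
    e("Infusion Drug", "medication", "Fentanyl (mcg/hr)"),
    e("Infusion Drug", "medication", "Midazolam (mg/hr)"),
    e("Infusion Drug", "medication", "Dexmedetomidine (mcg/kg/hr)"),
    # --- distractors ---
    e("Medication", "distractor", "LOPRESSOR"),
    e("Medication", "distractor", "ASPIRIN EC"),
    e("Medication", "distractor", "LASIX"),
    e("Medication", "distractor", "PANTOPRAZOLE"),
    e("Medication", "distractor", "HEPARIN SODIUM"),
    e("Medication", "distractor", "METFORMIN"),
    e("Medication", "distractor", "LISINOPRIL"),
    e("Medication", "distractor", "ATORVASTATIN"),
    e("Infusion Drug", "distractor", "Amiodarone (mg/min)"),
    e("Infusion Drug", "distractor", "Norepinephrine (mcg/min)"),
    e("Infusion Drug", "distractor", "Insulin (units/hr)"),
    e("Infusion Drug", "distractor", "Nitroglycerin (mcg/min)"),
    e("Infusion Drug", "distractor", "Vasopressin (units/min)"),
    e("Nurse Charting", "distractor", "Heart Rate", "88"),
    e("Nurse Charting", "distractor", "Temperature (C)", "37.1"),
    e("Nurse Charting", "distractor", "Pain Score", "3"),
    e("Nurse Charting", "distractor", "GCS Total", "15"),
    e("Nurse Charting", "distractor", "O2 Saturation", "97"),
    e("Nurse Charting", "distractor", "Respiratory Rate", "18"),
    e("Nurse Charting", "distractor", "Invasive BP Systolic", "120"),
    e("Nurse Charting", "distractor", "Bedside Glucose", "142"),
    e("Nurse Care", "distractor", "emergency equipment at bedside"),
    e("Nurse Care", "distractor", "fall precautions in place"),
    e("Nurse Care", "distractor", "turned and repositioned"),
    e("Nurse Care", "distractor", "oral care provided"),
    e("Nurse Care", "distractor", "restraints not in use"),
    e("Care Plan General", "distractor", "Route-Status", "Oral - low sodium"),
    e("Care Plan General", "distractor", "Activity", "Bedrest"),
    e("Care Plan General", "distractor", "Safety/Restraints", "Fall precautions"),
    e("Care Plan General", "distractor", "Psychosocial Status", "Anxious"),
    e("Note", "distractor", "denies fevers", "denies fevers"),
    e("Note", "distractor", "family meeting", "discussed goals of care"),
    e("Note", "distractor", "admission note", "admitted from ED"),
    e("Respiratory Charting", "distractor", "respFlowPtVentData", "SaO2", "25"),
    e("Respiratory Charting", "distractor", "respFlowPtVentData", "RR Patient", "22"),
    e("Respiratory Charting", "distractor", "respMisc", "Secretions", "thick"),
    e("Treatment", "distractor", "cardiovascular|myocardial ischemia / infarction|antiplatelet agent|aspirin"),
    e("Treatment", "distractor", "renal|electrolyte correction|potassium"),
    e("Treatment", "distractor", "gastrointestinal|medications|stress ulcer prophylaxis"),
    e("Treatment", "distractor", "neurologic|pain / agitation / altered mentation|analgesics")
  )
  bank <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  for (col in all_field_columns()) {
    if (!col %in% names(bank)) bank[[col]] <- NA_character_
  }
  rec <- bank |>
    dplyr::mutate(encounter_id = "bank", offset_minutes = 0L) |>
    dplyr::select("encounter_id", "table", "offset_minutes", dplyr::all_of(all_field_columns()))
  bank$concept <- build_concepts(rec)$concept
  dplyr::select(
    bank, "table", "category", "concept",
    dplyr::all_of(all_field_columns())
  )
}

#' @rdname default_concept_bank
#' @param bank a concept-bank tibble, as returned by [default_concept_bank()].
#' @return `lexicon_from_bank()` and `default_lexicon()` return the
#'   corresponding [relevance_lexicon()].
#' @export
lexicon_from_bank <- function(bank) {
  pick <- function(cat) bank$concept[bank$category == cat]
  relevance_lexicon(
    imv = pick("IMV"),
    nippv = pick("NIPPV"),
    hfni = pick("HFNI"),
    medications = pick("medication"),
    distractors = pick("distractor")
  )
}

#' @rdname default_concept_bank
#' @export
default_lexicon <- function() lexicon_from_bank(default_concept_bank())
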