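#' Source-table registry
#'
#' The pipeline consumes nine eICU-style source tables. Each table contributes
#' a templated "constructed concept" built from a fixed, ordered set of
#' descriptive columns, and carries its records' timing in a table-specific
#' offset column (integer minutes relative to ICU admission; negative values
#' are permitted and ordered normally). `source_tables()` returns the
#' registry: display name, file name, offset column, and the template fields
#' in concept order.
#'
#' @return A tibble with columns `table` (display name), `file` (delimited
#'   file name used on disk), `offset_col` (per-table offset column name) and
#'   `fields` (list column of template column names, in concept order).
#' @examples
#' source_tables()
#' @export
source_tables <- function() {
  tibble::tibble(
    table = c(
      "Care Plan General", "Infusion Drug", "Medication", "Note",
      "Nurse Care", "Nurse Charting", "Respiratory Care",
      "Respiratory Charting", "Treatment"
    ),
    file = c(
      "carePlanGeneral.csv", "infusionDrug.csv", "medication.csv", "note.csv",
      "nurseCare.csv", "nurseCharting.csv", "respiratoryCare.csv",
      "respiratoryCharting.csv", "treatment.csv"
    ),
    offset_col = c(
      "cplitemoffset", "infusionoffset", "drugstartoffset", "noteoffset",
      "nursecareentryoffset", "nursingchartoffset", "respcarestatusoffset",
      "respchartoffset", "treatmentoffset"
    ),
    fields = list(
      c("cplgroup", "cplitemvalue"),
      "drugname",
      "drugname",
      c("notevalue", "notetext"),
      "cellattributevalue",
      c("nursingchartcelltypevalname", "nursingchartvalue"),
      "airwaytype",
      c("respcharttypecat", "respchartvaluelabel", "respchartvalue"),
      "treatmentstring"
    )
  )
}

#' @rdname source_tables
#' @export
source_table_names <- function() source_tables()$table

# all distinct template field columns, in registry order
all_field_columns <- function() {
  unique(unlist(source_tables()$fields, use.names = FALSE))
}

#' Create raw EHR records
#'
#' Records are kept in one long tibble: identifier, source table, offset in
#' minutes, and one column per template field (NA where a field does not
#' belong to the record's table). `raw_records()` builds a validated record
#' tibble from loose vectors; `empty_records()` returns the zero-row
#' skeleton.
#'
#' @param encounter_id character vector of encounter identifiers.
#' @param table character vector of source-table display names (see
#'   [source_tables()]).
#' @param offset_minutes integer vector, minutes from ICU admission.
#' @param ... named character vectors for template field columns
#'   (e.g. `drugname = "LOPRESSOR"`). Fields a table does not use may be
#'   omitted; fields its template requires must be present and non-NA
#'   (empty strings are allowed).
#' @return A record tibble.
#' @examples
#' raw_records("e1", "Medication", 120, drugname = "LOPRESSOR")
#' @export
raw_records <- function(encounter_id, table, offset_minutes, ...) {
  fields <- list(...)
  bad <- setdiff(names(fields), all_field_columns())
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Unknown template field column(s): ", paste(bad, collapse = ", ")),
      class = "resppheno_malformed_record"
    )
  }
  out <- tibble::tibble(
    encounter_id = as.character(encounter_id),
    table = as.character(table),
    offset_minutes = as.integer(offset_minutes)
  )
  for (col in all_field_columns()) {
    out[[col]] <- if (col %in% names(fields)) as.character(fields[[col]]) else NA_character_
  }
  validate_records(out)
  out
}

#' @rdname raw_records
#' @export
empty_records <- function() {
  raw_records(character(), character(), integer())
}

validate_records <- function(records, call = rlang::caller_env()) {
  need <- c("encounter_id", "table", "offset_minutes", all_field_columns())
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Record tibble is missing column(s): ", paste(missing, collapse = ", ")),
      class = "resppheno_malformed_record", call = call
    )
  }
  unknown <- setdiff(unique(records$table), source_table_names())
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Unknown source table(s): ", paste(unknown, collapse = ", ")),
      class = "resppheno_unsupported_table", call = call
    )
  }
  invisible(records)
}
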