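#' Build constructed concepts from raw records
#'
#' Every record is rendered as a "constructed concept": the string
#' `"Source = <table>; Concept = <fields>"`, where `<fields>` are the
#' record's template column values joined with `": "` in the table's fixed
#' column order (see [source_tables()]). Identity is exact, case-sensitive
#' string equality; no normalisation is applied beyond removing trailing line
#' breaks from field values (and collapsing internal line breaks in the Note
#' table's free text to single spaces, so one concept always occupies one
#' line).
#'
#' @param records a record tibble (see [raw_records()]).
#' @return `build_concepts()` returns `records` with two columns appended:
#'   `concept` (the constructed-concept text) and `source_table` (alias of
#'   `table`, kept so concept tables remain self-describing after the record
#'   columns are dropped).
#' @examples
#' r <- raw_records(
#'   "e1", "Nurse Charting", 30,
#'   nursingchartcelltypevalname = "O2 Admin Device",
#'   nursingchartvalue = "BiPAP/CPAP"
#' )
#' build_concepts(r)$concept
#' @export
build_concepts <- function(records) {
  validate_records(records)
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, concept = character(), source_table = character()))
  }
  reg <- source_tables()
  concept <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(reg))) {
    tbl <- reg$table[i]
    rows <- which(records$table == tbl)
    if (length(rows) == 0) next
    flds <- reg$fields[[i]]
    vals <- lapply(flds, function(f) {
      v <- records[[f]][rows]
      if (anyNA(v)) {
        rlang::abort(
          paste0("Missing template field '", f, "' for table '", tbl, "'"),
          class = "resppheno_malformed_record"
        )
      }
      v <- sub("[\r\n]+$", "", v)
      if (f == "notetext") v <- gsub("[\r\n]+", " ", v)
      v
    })
    joined <- do.call(paste, c(vals, sep = ": "))
    concept[rows] <- paste0("Source = ", tbl, "; Concept = ", joined)
  }
  dplyr::mutate(records, concept = concept, source_table = .data$table)
}

#' Enumerate the distinct constructed concepts of a dataset
#'
#' Deduplicates the constructed concepts across all records (all encounters
#' pooled), keeping the source table and the number of supporting records.
#' The result is order-independent and idempotent: concepts compare equal iff
#' their full text strings are identical.
#'
#' @inheritParams build_concepts
#' @return A tibble with columns `concept`, `source_table`, `n_records`,
#'   sorted by `concept` text.
#' @export
distinct_concepts <- function(records) {
  built <- build_concepts(records)
  built |>
    dplyr::count(.data$concept, .data$source_table, name = "n_records") |>
    dplyr::arrange(.data$concept) |>
    dplyr::select("concept", "source_table", "n_records")
}
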