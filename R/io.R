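#' Write a cohort to eICU-style delimited tables
#'
#' Emits one CSV per source table (encounter id column `patientunitstayid`,
#' the table's own offset column, and its template columns), a `patient.csv`
#' (`patientunitstayid`, `uniquepid`, `age`, `unitvisitnumber`) and, when
#' truths are given, a `truths.jsonl` with one JSON object per encounter.
#' Empty cohorts still produce all nine table files with headers only, so the
#' directory always round-trips through [read_ehr_tables()].
#'
#' @param records record tibble.
#' @param encounters encounter tibble.
#' @param dir output directory (created if needed).
#' @param truths optional truths tibble from [generate_cohort()].
#' @return Invisibly, the written file paths.
#' @export
write_cohort_tables <- function(records, encounters, dir, truths = NULL) {
  validate_records(records)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- source_tables()
  paths <- character()
  for (i in seq_len(nrow(reg))) {
    rows <- records[records$table == reg$table[i], , drop = FALSE]
    out <- tibble::tibble(patientunitstayid = rows$encounter_id)
    out[[reg$offset_col[i]]] <- rows$offset_minutes
    for (f in reg$fields[[i]]) out[[f]] <- rows[[f]]
    path <- file.path(dir, reg$file[i])
    readr::write_csv(out, path, na = "")
    paths <- c(paths, path)
  }
  pat <- file.path(dir, "patient.csv")
  readr::write_csv(
    tibble::tibble(
      patientunitstayid = encounters$encounter_id,
      uniquepid = encounters$patient_id,
      age = encounters$age_years,
      unitvisitnumber = encounters$admit_order
    ),
    pat
  )
  paths <- c(paths, pat)
  if (!is.null(truths)) {
    tp <- file.path(dir, "truths.jsonl")
    lines <- vapply(seq_len(nrow(truths)), function(i) {
      jsonlite::toJSON(
        list(
          encounter_id = truths$encounter_id[i],
          phenotype = truths$phenotype[i],
          eligible = truths$eligible[i],
          episode_offsets = truths$episode_offsets[[i]]
        ),
        auto_unbox = TRUE
      )
    }, character(1))
    writeLines(lines, tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read eICU-style delimited tables into the record model
#'
#' Reads whichever of the nine expected table files are present (missing
#' tables produce a warning and are skipped), maps each table's columns onto
#' the shared record model, and parses offsets as integers. Rows whose offset
#' does not parse are counted, reported in one warning, and skipped; if more
#' than `corruption_threshold` of a file's rows are malformed the read
#' aborts.
#'
#' @param dir directory containing the table files.
#' @param corruption_threshold maximum tolerated fraction of malformed rows
#'   per file.
#' @return List with `records` and `encounters` tibbles (and `truths` if a
#'   `truths.jsonl` is present, else NULL).
#' @export
read_ehr_tables <- function(dir, corruption_threshold = 0.5) {
  reg <- source_tables()
  recs <- list()
  for (i in seq_len(nrow(reg))) {
    path <- file.path(dir, reg$file[i])
    if (!file.exists(path)) {
      warning("Missing table file: ", reg$file[i], " (skipped)", call. = FALSE)
      next
    }
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), progress = FALSE
    )
    off <- suppressWarnings(as.integer(raw[[reg$offset_col[i]]]))
    bad <- is.na(off)
    if (any(bad)) {
      if (mean(bad) > corruption_threshold) {
        rlang::abort(
          paste0("Corrupt table ", reg$file[i], ": ", sum(bad), "/", nrow(raw), " malformed rows"),
          class = "resppheno_io_error"
        )
      }
      warning(sum(bad), " malformed row(s) skipped in ", reg$file[i], call. = FALSE)
      raw <- raw[!bad, , drop = FALSE]
      off <- off[!bad]
    }
    if (nrow(raw) == 0) next
    args <- stats::setNames(
      lapply(reg$fields[[i]], function(f) raw[[f]]),
      reg$fields[[i]]
    )
    recs[[length(recs) + 1]] <- do.call(raw_records, c(
      list(
        encounter_id = raw$patientunitstayid,
        table = reg$table[i],
        offset_minutes = off
      ),
      args
    ))
  }
  records <- if (length(recs) > 0) dplyr::bind_rows(recs) else empty_records()
  pat_path <- file.path(dir, "patient.csv")
  encounters <- if (file.exists(pat_path)) {
    pat <- readr::read_csv(
      pat_path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    tibble::tibble(
      encounter_id = pat$patientunitstayid,
      patient_id = pat$uniquepid,
      age_years = pat$age,
      admit_order = as.integer(pat$unitvisitnumber)
    )
  } else {
    warning("No patient.csv found; encounter table is empty", call. = FALSE)
    tibble::tibble(
      encounter_id = character(), patient_id = character(),
      age_years = character(), admit_order = integer()
    )
  }
  truth_path <- file.path(dir, "truths.jsonl")
  truths <- if (file.exists(truth_path)) {
    rows <- lapply(readLines(truth_path), jsonlite::fromJSON)
    tibble::tibble(
      encounter_id = vapply(rows, `[[`, character(1), "encounter_id"),
      phenotype = vapply(rows, `[[`, character(1), "phenotype"),
      eligible = vapply(rows, `[[`, logical(1), "eligible"),
      episode_offsets = lapply(rows, `[[`, "episode_offsets")
    )
  }
  list(records = records, encounters = encounters, truths = truths)
}
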