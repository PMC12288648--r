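# Shared fixtures: everything is built in code at test time.

fixture_bank <- default_concept_bank()
fixture_lexicon <- lexicon_from_bank(fixture_bank)
fixture_templates <- default_templates()

# Records built from the i-th bank concept of each requested category, so
# concepts within one call are distinct per category unless i repeats.
bank_rec <- function(category, i, offset, encounter_id = "e1", bank = fixture_bank) {
  rows <- which(bank$category == category)
  stopifnot(length(rows) >= max(i))
  idx <- rows[i]
  out <- bank[idx, c("table", resppheno:::all_field_columns()), drop = FALSE]
  out <- dplyr::mutate(out,
    encounter_id = encounter_id,
    offset_minutes = as.integer(offset),
    .before = 1
  )
  dplyr::select(
    out, "encounter_id", "table", "offset_minutes",
    dplyr::all_of(resppheno:::all_field_columns())
  )
}

# e.g. micro_records(IMV = c(50, 300), medication = 60, NIPPV = c(100, 200))
micro_records <- function(..., encounter_id = "e1") {
  spec <- list(...)
  dplyr::bind_rows(purrr::imap(spec, function(offsets, cat) {
    bank_rec(cat, seq_along(offsets), offsets, encounter_id = encounter_id)
  }))
}

# a fixed backend answering from a per-task lookup table, for truth-table tests
fixed_backend <- function(answers) {
  b <- structure(
    list(
      label = "fixed", answers = answers,
      calls = new.env(parent = emptyenv())
    ),
    class = c("test_fixed_backend", "resppheno_backend")
  )
  registerS3method(
    "backend_classify", "test_fixed_backend",
    function(backend, prompt, payload, template) {
      decision <- backend$answers[[template$task]]
      raw <- paste0("stub reasoning\n", template$answer_marker, ": ", decision)
      tibble::tibble(
        raw_text = raw,
        decision = parse_final_answer(raw, template),
        latency_seconds = 0
      )
    },
    envir = asNamespace("resppheno")
  )
  b
}
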