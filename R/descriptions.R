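#' Build an encounter's constructed description
#'
#' A constructed description presents an encounter's selected concepts to a
#' classifier with all timing generalised to order: records are filtered to
#' the selected concepts, each distinct concept is ranked by its first
#' occurrence (minimum offset; ties broken by concept text for determinism),
#' and rendered one per line as `"<rank>: <concept>"`. Descriptions carry no
#' offsets and no encounter identifiers, so identical clinical courses
#' produce identical texts and need only one classification between them.
#'
#' @param records record tibble for a single encounter.
#' @param selected_concepts character vector of selected concept texts.
#' @return A single string (empty when the encounter has no selected
#'   concepts).
#' @export
build_description <- function(records, selected_concepts) {
  built <- build_concepts(records)
  built <- built[built$concept %in% selected_concepts, , drop = FALSE]
  if (nrow(built) == 0) {
    return("")
  }
  firsts <- built |>
    dplyr::summarise(
      first_offset = min(.data$offset_minutes),
      .by = "concept"
    ) |>
    dplyr::arrange(.data$first_offset, .data$concept)
  paste0(seq_len(nrow(firsts)), ": ", firsts$concept, collapse = "\n")
}

#' @rdname build_description
#' @param encounters optional encounter tibble; when given, encounters with
#'   no qualifying records receive an empty description instead of being
#'   dropped.
#' @return `build_descriptions()` returns a tibble of `encounter_id`,
#'   `description` covering every encounter.
#' @export
build_descriptions <- function(records, selected_concepts, encounters = NULL) {
  built <- build_concepts(records)
  built <- built[built$concept %in% selected_concepts, , drop = FALSE]
  desc <- built |>
    dplyr::summarise(
      first_offset = min(.data$offset_minutes),
      .by = c("encounter_id", "concept")
    ) |>
    dplyr::arrange(.data$first_offset, .data$concept) |>
    dplyr::summarise(
      description = paste0(dplyr::row_number(), ": ", .data$concept, collapse = "\n"),
      .by = "encounter_id"
    )
  ids <- if (is.null(encounters)) {
    unique(records$encounter_id)
  } else {
    encounters$encounter_id
  }
  tibble::tibble(encounter_id = ids) |>
    dplyr::left_join(desc, by = "encounter_id") |>
    dplyr::mutate(description = dplyr::coalesce(.data$description, ""))
}

# Invert a description back into (rank, concept) pairs. Ranks double as
# pseudo-offsets: within a description, rank order is first-occurrence order.
parse_description <- function(text) {
  if (!nzchar(text)) {
    return(tibble::tibble(rank = integer(), concept = character()))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  m <- regmatches(lines, regexec("^([0-9]+): (.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    rlang::abort("Malformed description line(s)", class = "resppheno_malformed_record")
  }
  tibble::tibble(
    rank = as.integer(vapply(m, `[`, character(1), 2)),
    concept = vapply(m, `[`, character(1), 3)
  )
}

#' Phenotype a constructed description with the rule engine
#'
#' Applies the reference therapy criteria to a description's concept lines,
#' using each concept's rank as its pseudo-offset (the description's only
#' notion of time). This is how the oracle backend labels descriptions.
#'
#' @param text a constructed-description string.
#' @param lexicon a [relevance_lexicon()].
#' @return A phenotype label.
#' @export
phenotype_from_description <- function(text, lexicon) {
  d <- parse_description(text)
  label_from_events(d$rank, concept_category(d$concept, lexicon))
}

#' Phenotype unique constructed descriptions
#'
#' Classifies each distinct non-empty description text exactly once through
#' the backend (empty descriptions are labeled `"None"` without a call —
#' there is no therapy evidence to present). Parsed labels outside the
#' eight-class vocabulary surface as `"UNPARSEABLE"` per the template parser.
#'
#' @param descriptions character vector (or the tibble from
#'   [build_descriptions()]) of description texts; duplicates are collapsed.
#' @param backend a classification backend (see [backends]).
#' @param template the phenotype [prompt_template()].
#' @param unparseable policy for unparseable responses: `"keep"` (default)
#'   records `"UNPARSEABLE"`, `"error"` aborts listing the descriptions.
#' @return A tibble of `description`, `phenotype`, `latency_seconds` with one
#'   row per unique description.
#' @export
phenotype_descriptions <- function(descriptions, backend, template,
                                   unparseable = c("keep", "error")) {
  unparseable <- match.arg(unparseable)
  if (is.data.frame(descriptions)) descriptions <- descriptions$description
  uniq <- unique(descriptions)
  res <- purrr::map(uniq, function(d) {
    if (!nzchar(d)) {
      return(tibble::tibble(raw_text = NA_character_, decision = "None", latency_seconds = 0))
    }
    prompt <- assemble_prompt(template, d)
    backend_classify(backend, prompt, d, template)
  })
  out <- tibble::tibble(
    description = uniq,
    phenotype = vapply(res, function(r) r$decision, character(1)),
    latency_seconds = vapply(res, function(r) r$latency_seconds, numeric(1))
  )
  if (unparseable == "error" && any(out$phenotype == "UNPARSEABLE")) {
    n_bad <- sum(out$phenotype == "UNPARSEABLE")
    rlang::abort(
      paste0(n_bad, " description(s) received unparseable responses"),
      class = "resppheno_backend_error"
    )
  }
  out
}

#' Map description labels back to encounters
#'
#' @param desc_labels tibble from [phenotype_descriptions()].
#' @param encounter_descriptions tibble from [build_descriptions()]
#'   (`encounter_id`, `description`).
#' @return Tibble of `encounter_id`, `phenotype`; every encounter must have a
#'   labeled description or an integrity error is raised.
#' @export
map_to_encounters <- function(desc_labels, encounter_descriptions) {
  out <- dplyr::left_join(encounter_descriptions, desc_labels, by = "description")
  if (anyNA(out$phenotype)) {
    rlang::abort(
      paste0(sum(is.na(out$phenotype)), " encounter(s) have no labeled description"),
      class = "resppheno_integrity_error"
    )
  }
  dplyr::select(out, "encounter_id", "phenotype")
}

#' Run the description-phenotyping stage end to end
#'
#' Builds descriptions for every encounter from the selected concepts,
#' phenotypes the unique texts through the backend, and maps labels back to
#' encounters.
#'
#' @param records cohort record tibble.
#' @param encounters encounter tibble (already cohort-filtered).
#' @param selected_concepts character vector of selected concept texts.
#' @inheritParams phenotype_descriptions
#' @return List with `encounter_labels` (`encounter_id`, `phenotype`),
#'   `descriptions`, `desc_labels`, and `n_backend_calls` (one per unique
#'   non-empty description).
#' @export
apply_algorithm <- function(records, encounters, selected_concepts, backend,
                            template, unparseable = "keep") {
  descriptions <- build_descriptions(records, selected_concepts, encounters)
  desc_labels <- phenotype_descriptions(
    descriptions, backend, template,
    unparseable = unparseable
  )
  list(
    encounter_labels = map_to_encounters(desc_labels, descriptions),
    descriptions = descriptions,
    desc_labels = desc_labels,
    n_backend_calls = sum(nzchar(desc_labels$description))
  )
}
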