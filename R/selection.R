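#' Classify one constructed concept with the two relevance prompts
#'
#' Every distinct concept is judged twice — once against the respiratory
#' support therapy definitions and once against the intubation-related
#' medication definitions — and the final decision is the OR of the two: YES
#' if at least one response is YES, NO otherwise. Unparseable responses are
#' treated as NO by default (`"as_no"`), or can abort (`"error"`).
#'
#' @param concept a constructed-concept string.
#' @param backend a classification backend (see [backends]).
#' @param templates list with `therapy` and `medication`
#'   [prompt_template()]s, as from [default_templates()].
#' @param unparseable `"as_no"` (default) or `"error"`.
#' @return One-row tibble: `concept`, `therapy_decision`,
#'   `medication_decision`, `final`, `therapy_latency`, `medication_latency`.
#' @export
classify_concept <- function(concept, backend, templates,
                             unparseable = c("as_no", "error")) {
  unparseable <- match.arg(unparseable)
  one <- function(template) {
    res <- backend_classify(
      backend, assemble_prompt(template, concept), concept, template
    )
    if (res$decision == "UNPARSEABLE" && unparseable == "error") {
      rlang::abort(
        paste0("Unparseable response for concept: ", concept),
        class = "resppheno_backend_error"
      )
    }
    res
  }
  th <- one(templates$therapy)
  med <- one(templates$medication)
  tibble::tibble(
    concept = concept,
    therapy_decision = th$decision,
    medication_decision = med$decision,
    final = if (th$decision == "YES" || med$decision == "YES") "YES" else "NO",
    therapy_latency = th$latency_seconds,
    medication_latency = med$latency_seconds
  )
}

#' Select relevant concepts with a classification backend
#'
#' Runs [classify_concept()] over a set of distinct concepts (classification
#' is global, by concept text, not per encounter; results are joined back to
#' records downstream). Backend failures are collected per concept and the
#' stage aborts only when their fraction exceeds `failure_threshold`.
#'
#' @param concepts character vector (or [distinct_concepts()] tibble) of
#'   concept texts; duplicates are collapsed.
#' @inheritParams classify_concept
#' @param failure_threshold maximum tolerated fraction of failed concepts.
#' @return An object of class `concept_selection`: list with `selected`
#'   (character vector of concepts whose final decision is YES), `decisions`
#'   (the per-concept tibble), `latency` (per-prompt and overall means, see
#'   [latency_summary()]) and `failures`.
#' @export
select_concepts <- function(concepts, backend, templates,
                            unparseable = "as_no", failure_threshold = 0) {
  if (is.data.frame(concepts)) concepts <- concepts$concept
  concepts <- unique(concepts)
  failures <- list()
  rows <- purrr::map(concepts, function(cc) {
    tryCatch(
      classify_concept(cc, backend, templates, unparseable = unparseable),
      error = function(e) {
        failures[[length(failures) + 1]] <<- tibble::tibble(
          concept = cc, error = conditionMessage(e)
        )
        NULL
      }
    )
  })
  failures <- dplyr::bind_rows(failures)
  if (length(concepts) > 0 && nrow(failures) / length(concepts) > failure_threshold) {
    rlang::abort(
      paste0(
        nrow(failures), "/", length(concepts),
        " concepts failed classification (threshold exceeded)"
      ),
      class = "resppheno_backend_error"
    )
  }
  decisions <- dplyr::bind_rows(rows)
  if (nrow(decisions) == 0) {
    decisions <- tibble::tibble(
      concept = character(), therapy_decision = character(),
      medication_decision = character(), final = character(),
      therapy_latency = numeric(), medication_latency = numeric()
    )
  }
  latency <- if (nrow(decisions) > 0) {
    latency_summary(tibble::tibble(
      prompt = rep(c("therapy", "medication"), each = nrow(decisions)),
      latency_seconds = c(decisions$therapy_latency, decisions$medication_latency)
    ))
  } else {
    tibble::tibble(prompt = character(), n_calls = integer(), mean_latency_seconds = numeric())
  }
  structure(
    list(
      selected = decisions$concept[decisions$final == "YES"],
      decisions = decisions,
      latency = latency,
      failures = failures
    ),
    class = "concept_selection"
  )
}

#' @export
print.concept_selection <- function(x, ...) {
  cat(
    "<concept_selection>", length(x$selected), "of",
    nrow(x$decisions), "concepts selected\n"
  )
  if (nrow(x$failures) > 0) cat("  failures:", nrow(x$failures), "\n")
  print(as.data.frame(x$latency), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.phenotype_eval
#' @method tidy concept_selection
#' @export
tidy.concept_selection <- function(x, ...) {
  x$decisions
}

#' @rdname tidy.phenotype_eval
#' @method glance concept_selection
#' @export
glance.concept_selection <- function(x, ...) {
  tibble::tibble(
    n_concepts = nrow(x$decisions),
    n_selected = length(x$selected),
    n_failures = nrow(x$failures),
    mean_latency_seconds =
      x$latency$mean_latency_seconds[x$latency$prompt == "overall"]
  )
}
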