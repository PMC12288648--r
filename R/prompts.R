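#' Chain-of-thought prompt templates
#'
#' Each classification task (therapy-concept relevance, medication-concept
#' relevance, description phenotyping) is driven by a template: a preamble
#' holding task definitions and a `{payload}` placeholder, an ordered series
#' of chain-of-thought questions that walk the model to its decision, and a
#' final question whose parsed answer is the decision. Templates ship as
#' editable YAML files (see `system.file("templates", package = "resppheno")`)
#' because prompt wording is configuration, not code; the parser keys off the
#' template's own `answer_marker`.
#'
#' @param task one of `"concept-therapy"`, `"concept-medication"`,
#'   `"phenotype"`.
#' @param preamble definition text; must contain the `{payload}` placeholder
#'   exactly once. Other `{name}` placeholders are resolved from `fields` at
#'   assembly time.
#' @param cot_questions character vector of intermediate questions (may be
#'   empty).
#' @param final_question the question whose answer is parsed; it is always
#'   placed last.
#' @param answer_vocabulary allowed final answers (e.g. `c("YES", "NO")` or
#'   the eight phenotype labels).
#' @param answer_marker string that introduces the final answer in a
#'   response; parsing looks after its last occurrence, case-insensitively.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(task, preamble, cot_questions = character(),
                            final_question, answer_vocabulary,
                            answer_marker = "FINAL ANSWER") {
  if (is.null(final_question) || !nzchar(final_question)) {
    rlang::abort("final_question must be a non-empty string",
      class = "resppheno_template_error"
    )
  }
  if (length(answer_vocabulary) == 0) {
    rlang::abort("answer_vocabulary must be non-empty",
      class = "resppheno_template_error"
    )
  }
  structure(
    list(
      task = task,
      preamble = preamble,
      cot_questions = as.character(cot_questions),
      final_question = final_question,
      answer_vocabulary = as.character(answer_vocabulary),
      answer_marker = answer_marker
    ),
    class = "prompt_template"
  )
}

#' @rdname prompt_template
#' @param path path to a YAML template file with keys matching the
#'   constructor arguments.
#' @export
read_prompt_template <- function(path) {
  y <- yaml::read_yaml(path)
  prompt_template(
    task = y$task,
    preamble = y$preamble,
    cot_questions = unlist(y$cot_questions),
    final_question = y$final_question,
    answer_vocabulary = unlist(y$answer_vocabulary),
    answer_marker = y$answer_marker %||% "FINAL ANSWER"
  )
}

#' @rdname prompt_template
#' @return `default_templates()` returns a named list of the three shipped
#'   templates (`therapy`, `medication`, `phenotype`).
#' @export
default_templates <- function() {
  dir <- system.file("templates", package = "resppheno")
  list(
    therapy = read_prompt_template(file.path(dir, "concept-therapy.yaml")),
    medication = read_prompt_template(file.path(dir, "concept-medication.yaml")),
    phenotype = read_prompt_template(file.path(dir, "phenotype.yaml"))
  )
}

#' Assemble a prompt from a template and payload
#'
#' Substitutes `fields` into any named placeholders, verifies nothing is
#' left unresolved, then inserts the payload verbatim (exactly once) and
#' appends the chain-of-thought questions in order with the final question
#' last.
#'
#' @param template a [prompt_template()].
#' @param payload the text to classify (a constructed concept or
#'   description).
#' @param fields named list of values for additional `{name}` placeholders.
#' @return A single prompt string.
#' @export
assemble_prompt <- function(template, payload, fields = list()) {
  parts <- c(template$preamble, template$cot_questions, template$final_question)
  for (nm in names(fields)) {
    parts <- gsub(paste0("{", nm, "}"), as.character(fields[[nm]]), parts, fixed = TRUE)
  }
  leftover <- setdiff(
    unique(unlist(regmatches(parts, gregexpr("\\{[a-zA-Z_][a-zA-Z0-9_]*\\}", parts)))),
    "{payload}"
  )
  if (length(leftover) > 0) {
    rlang::abort(
      paste0("Unresolved placeholder(s): ", paste(leftover, collapse = ", ")),
      class = "resppheno_template_error"
    )
  }
  n_slots <- sum(lengths(gregexpr("{payload}", parts, fixed = TRUE)) *
    (regexpr("{payload}", parts, fixed = TRUE) > 0))
  if (n_slots != 1) {
    rlang::abort("Template must contain the {payload} placeholder exactly once",
      class = "resppheno_template_error"
    )
  }
  parts <- sub("{payload}", payload, parts, fixed = TRUE)
  paste(parts, collapse = "\n\n")
}

#' Parse the final answer out of a model response
#'
#' Looks at the text after the last (case-insensitive) occurrence of the
#' template's answer marker and matches the answer vocabulary there,
#' case-insensitively on word boundaries. When reasoning text mentions
#' several vocabulary tokens, the last one wins (ties on position go to the
#' longer token). If the marker or any vocabulary token is absent the value
#' `"UNPARSEABLE"` is returned — it is a value, not an error, so responses
#' stay auditable.
#'
#' @param raw_text the backend's raw response text.
#' @param template a [prompt_template()].
#' @return One of `template$answer_vocabulary` (canonical casing) or
#'   `"UNPARSEABLE"`.
#' @examples
#' tpl <- prompt_template(
#'   task = "concept-therapy", preamble = "{payload}",
#'   final_question = "FINAL ANSWER (YES or NO):",
#'   answer_vocabulary = c("YES", "NO")
#' )
#' parse_final_answer("reasoning... Final answer: no.", tpl)
#' @export
parse_final_answer <- function(raw_text, template) {
  if (is.na(raw_text) || !nzchar(raw_text)) {
    return("UNPARSEABLE")
  }
  marker_hits <- stringr::str_locate_all(
    raw_text,
    stringr::fixed(template$answer_marker, ignore_case = TRUE)
  )[[1]]
  if (nrow(marker_hits) == 0) {
    return("UNPARSEABLE")
  }
  segment <- substring(raw_text, marker_hits[nrow(marker_hits), "end"] + 1)
  best <- NULL
  best_start <- -1L
  best_len <- -1L
  for (token in template$answer_vocabulary) {
    hits <- stringr::str_locate_all(
      segment,
      stringr::regex(
        paste0("\\b", stringr::str_replace_all(token, "([\\W])", "\\\\\\1"), "\\b"),
        ignore_case = TRUE
      )
    )[[1]]
    if (nrow(hits) == 0) next
    s <- hits[nrow(hits), "start"]
    len <- nchar(token)
    if (s > best_start || (s == best_start && len > best_len)) {
      best <- token
      best_start <- s
      best_len <- len
    }
  }
  if (is.null(best)) "UNPARSEABLE" else best
}
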