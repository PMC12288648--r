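#' Run configuration
#'
#' Bundles everything one reproducible pipeline run needs: where the tables
#' live (or a generator config to synthesise them), the backend choice, the
#' prompt templates, output paths and policies. The configuration is hashed
#' and stamped, together with the seed, into every artifact the run writes.
#'
#' @param tables_dir directory of input tables (see [read_ehr_tables()]), or
#'   NULL to generate synthetic tables from `generator`.
#' @param out_dir directory for run artifacts.
#' @param backend one of `"oracle"`, `"noisy"`, `"ollama"`, or a backend
#'   object.
#' @param generator optional [generator_config()] used when `tables_dir` is
#'   NULL.
#' @param lexicon a [relevance_lexicon()]; defaults to the generator bank's
#'   lexicon (required for the rule-based reference labels and the test
#'   doubles).
#' @param templates template list as from [default_templates()].
#' @param flip_prob noise level for the `"noisy"` backend.
#' @param settings [decoding_settings()] for the `"ollama"` backend.
#' @param cache_dir optional response-cache directory (enables
#'   [backend_cached()]).
#' @param unparseable_concepts,unparseable_phenotypes policies for
#'   unparseable responses in the two stages.
#' @param seed integer seed recorded in provenance and used for generation
#'   and noise.
#' @return A `run_config` object.
#' @export
run_config <- function(tables_dir = NULL,
                       out_dir = tempfile("resppheno-run-"),
                       backend = "oracle",
                       generator = generator_config(seed = seed),
                       lexicon = NULL,
                       templates = default_templates(),
                       flip_prob = 0.1,
                       settings = NULL,
                       cache_dir = NULL,
                       unparseable_concepts = "as_no",
                       unparseable_phenotypes = "keep",
                       seed = 1L) {
  if (!is.null(tables_dir) && !dir.exists(tables_dir)) {
    rlang::abort(paste0("tables_dir does not exist: ", tables_dir),
      class = "resppheno_config_error"
    )
  }
  structure(
    list(
      tables_dir = tables_dir, out_dir = out_dir, backend = backend,
      generator = generator, lexicon = lexicon, templates = templates,
      flip_prob = flip_prob, settings = settings, cache_dir = cache_dir,
      unparseable_concepts = unparseable_concepts,
      unparseable_phenotypes = unparseable_phenotypes,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

resolve_backend <- function(config, lexicon) {
  b <- config$backend
  if (inherits(b, "resppheno_backend")) {
    return(b)
  }
  b <- switch(as.character(b),
    oracle = backend_oracle(lexicon),
    noisy = backend_noisy(lexicon, config$flip_prob, seed = config$seed),
    ollama = backend_ollama(config$settings),
    rlang::abort(paste0("Unknown backend: ", b), class = "resppheno_config_error")
  )
  if (!is.null(config$cache_dir)) b <- backend_cached(b, config$cache_dir)
  b
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in order — (optionally) generate synthetic tables,
#' read tables, build and deduplicate constructed concepts, select relevant
#' concepts through the backend, build and phenotype constructed
#' descriptions, map labels to encounters, and evaluate against the
#' rule-based reference labels — writing each stage's artifact to
#' `config$out_dir` stamped with the configuration hash and seed. A stage
#' failure halts the run with prior artifacts intact.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return List with `cohort_filtered` (encounters surviving the filters),
#'   `concepts`, `selection`, `apply`, `reference_labels`, `labels`
#'   (per-encounter predicted and reference phenotype), `eval`
#'   (a `phenotype_eval`), and `provenance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  for (nm in c("therapy", "medication", "phenotype")) {
    if (!inherits(config$templates[[nm]], "prompt_template")) {
      rlang::abort(paste0("Missing or invalid template: ", nm),
        class = "resppheno_config_error"
      )
    }
  }

  if (is.null(config$tables_dir)) {
    say("Generating synthetic cohort (", config$generator$n_patients, " patients)")
    cohort <- generate_cohort(config$generator)
    tables_dir <- file.path(config$out_dir, "tables")
    write_cohort_tables(cohort$records, cohort$encounters, tables_dir, cohort$truths)
    lexicon <- config$lexicon %||% cohort$lexicon
  } else {
    tables_dir <- config$tables_dir
    lexicon <- config$lexicon %||% default_lexicon()
  }

  say("Reading tables from ", tables_dir)
  tabs <- read_ehr_tables(tables_dir)
  records <- tabs$records
  encounters <- tabs$encounters

  kept <- encounters |>
    select_first_encounters() |>
    filter_adults()
  say(
    "Cohort filters: ", nrow(encounters), " encounters -> ", nrow(kept),
    " (first encounter per patient, adults only)"
  )

  concepts <- distinct_concepts(records)
  say("Constructed concepts: ", nrow(concepts), " distinct")
  readr::write_csv(concepts, file.path(config$out_dir, "concepts.csv"))

  backend <- resolve_backend(config, lexicon)
  selection <- select_concepts(
    concepts, backend, config$templates,
    unparseable = config$unparseable_concepts
  )
  say("Concepts selected: ", length(selection$selected), " of ", nrow(concepts))
  readr::write_csv(selection$decisions, file.path(config$out_dir, "concept_decisions.csv"))
  writeLines(selection$selected, file.path(config$out_dir, "selected_concepts.txt"))

  kept_records <- records[records$encounter_id %in% kept$encounter_id, , drop = FALSE]
  applied <- apply_algorithm(
    kept_records, kept, selection$selected, backend,
    config$templates$phenotype,
    unparseable = config$unparseable_phenotypes
  )
  say(
    "Unique descriptions: ", nrow(applied$desc_labels),
    " (", applied$n_backend_calls, " backend calls)"
  )
  readr::write_csv(applied$descriptions, file.path(config$out_dir, "descriptions.csv"))
  readr::write_csv(applied$encounter_labels, file.path(config$out_dir, "labels.csv"))

  reference <- reference_phenotypes(records, encounters, lexicon)
  labels <- dplyr::inner_join(
    dplyr::rename(applied$encounter_labels, predicted = "phenotype"),
    dplyr::rename(reference, reference = "phenotype"),
    by = "encounter_id"
  )
  per_prompt_lat <- dplyr::bind_rows(
    tibble::tibble(
      prompt = "therapy",
      latency_seconds = selection$decisions$therapy_latency
    ),
    tibble::tibble(
      prompt = "medication",
      latency_seconds = selection$decisions$medication_latency
    ),
    tibble::tibble(
      prompt = "phenotype",
      latency_seconds = applied$desc_labels$latency_seconds[
        nzchar(applied$desc_labels$description)
      ]
    )
  )
  eval <- evaluate_phenotypes(labels,
    truth = .data$reference, estimate = .data$predicted,
    latencies = per_prompt_lat
  )

  provenance <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    backend = backend$label,
    n_encounters_evaluated = nrow(labels),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(
    c(provenance, list(glance = as.list(glance(eval)))),
    file.path(config$out_dir, "run.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(tidy(eval), file.path(config$out_dir, "evaluation.csv"))

  list(
    cohort_filtered = kept, concepts = concepts, selection = selection,
    apply = applied, reference_labels = reference, labels = labels,
    eval = eval, provenance = provenance
  )
}
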