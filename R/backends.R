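#' Decoding settings for a live language-model backend
#'
#' Deterministic decoding is the default (temperature 0.0, top-p 0.99) so
#' responses stay inside the requested format and reruns are reproducible.
#'
#' @param model_name model tag known to the serving endpoint.
#' @param endpoint base URL of an Ollama-compatible HTTP endpoint.
#' @param temperature sampling temperature, `>= 0`.
#' @param top_p nucleus-sampling mass, in `(0, 1]`.
#' @param max_tokens optional cap on generated tokens.
#' @param retries number of retries on transport failure.
#' @param timeout per-call timeout in seconds.
#' @return A `decoding_settings` object.
#' @export
decoding_settings <- function(model_name,
                              endpoint = "http://localhost:11434",
                              temperature = 0.0,
                              top_p = 0.99,
                              max_tokens = NULL,
                              retries = 2L,
                              timeout = 120) {
  if (temperature < 0) {
    rlang::abort("temperature must be >= 0", class = "resppheno_config_error")
  }
  if (top_p <= 0 || top_p > 1) {
    rlang::abort("top_p must be in (0, 1]", class = "resppheno_config_error")
  }
  structure(
    list(
      model_name = model_name, endpoint = endpoint,
      temperature = temperature, top_p = top_p,
      max_tokens = max_tokens, retries = as.integer(retries), timeout = timeout
    ),
    class = "decoding_settings"
  )
}

new_backend <- function(subclass, label, ...) {
  structure(
    list(label = label, calls = new.env(parent = emptyenv()), ...),
    class = c(subclass, "resppheno_backend")
  )
}

#' Classification backends
#'
#' A backend answers one assembled prompt at a time and returns a one-row
#' tibble of `raw_text`, `decision` (a vocabulary token or `"UNPARSEABLE"`)
#' and `latency_seconds`. The pipeline depends on backends only through this
#' contract, so the deterministic `backend_oracle()` (answers from the known
#' lexicon / rule engine), the seeded `backend_noisy()` (oracle decisions
#' flipped with probability `flip_prob`), and the live [backend_ollama()] are
#' interchangeable. `backend_cached()` wraps any backend with an on-disk
#' response cache keyed by (backend label, prompt) so reruns make zero new
#' calls.
#'
#' The oracle answers concept tasks by set membership of the payload in the
#' lexicon's relevant sets, and the phenotype task by re-running the rule
#' engine on the description with each concept's rank as its pseudo-offset.
#' Its raw text ends with the template's answer marker followed by the
#' decision, so parsing round-trips exactly.
#'
#' @param lexicon a [relevance_lexicon()] the test doubles answer from.
#' @return A backend object.
#' @name backends
#' @export
backend_oracle <- function(lexicon) {
  new_backend("resppheno_backend_oracle", "oracle", lexicon = lexicon)
}

#' @rdname backends
#' @param flip_prob probability that the oracle's decision is flipped
#'   (binary tasks: complemented; phenotype task: replaced by a different
#'   label). Flips are derived deterministically from a hash of
#'   `(seed, task, payload)`, so they are seeded, order-independent and
#'   stable across reruns.
#' @param seed integer seed for the flip stream.
#' @export
backend_noisy <- function(lexicon, flip_prob, seed = 1L) {
  if (flip_prob < 0 || flip_prob > 1) {
    rlang::abort("flip_prob must be in [0, 1]", class = "resppheno_config_error")
  }
  new_backend("resppheno_backend_noisy", "noisy",
    lexicon = lexicon, flip_prob = flip_prob, seed = as.integer(seed)
  )
}

#' @rdname backends
#' @param settings a [decoding_settings()].
#' @export
backend_ollama <- function(settings) {
  stopifnot(inherits(settings, "decoding_settings"))
  new_backend("resppheno_backend_ollama", settings$model_name, settings = settings)
}

#' @rdname backends
#' @param backend any backend to wrap.
#' @param cache_dir directory for the JSON response cache.
#' @export
backend_cached <- function(backend, cache_dir) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  new_backend("resppheno_backend_cached", backend$label,
    inner = backend, cache_dir = cache_dir
  )
}

#' @rdname backends
#' @param x a backend.
#' @return `backend_calls()` returns the number of real classification calls
#'   the backend has answered (cache hits excluded).
#' @export
backend_calls <- function(x) {
  get0("n", envir = x$calls, ifnotfound = 0L)
}

bump_calls <- function(backend) {
  assign("n", backend_calls(backend) + 1L, envir = backend$calls)
}

#' @export
print.resppheno_backend <- function(x, ...) {
  cat("<resppheno_backend:", class(x)[1], "label:", x$label,
    "calls:", backend_calls(x), ">\n"
  )
  invisible(x)
}

#' Classify one payload through a backend
#'
#' Assembles nothing itself: callers pass the already-assembled `prompt`
#' (sent to live backends verbatim) together with the raw `payload` the test
#' doubles answer from.
#'
#' @param backend a backend object.
#' @param prompt the assembled prompt text.
#' @param payload the classified text (concept or description).
#' @param template the [prompt_template()] used, for answer parsing.
#' @return One-row tibble: `raw_text`, `decision`, `latency_seconds`.
#' @export
backend_classify <- function(backend, prompt, payload, template) {
  UseMethod("backend_classify")
}

oracle_decision <- function(lexicon, task, payload) {
  switch(task,
    "concept-therapy" = {
      if (payload %in% unlist(lexicon$therapy, use.names = FALSE)) "YES" else "NO"
    },
    "concept-medication" = {
      if (payload %in% lexicon$medications) "YES" else "NO"
    },
    "phenotype" = phenotype_from_description(payload, lexicon),
    rlang::abort(paste0("Unknown task: ", task), class = "resppheno_template_error")
  )
}

oracle_raw_text <- function(decision, template) {
  paste0(
    "Considering the definitions and the questions in order, the evidence ",
    "supports this conclusion.\n",
    template$answer_marker, ": ", decision
  )
}

respond <- function(backend, decision, template, t0) {
  bump_calls(backend)
  raw <- oracle_raw_text(decision, template)
  tibble::tibble(
    raw_text = raw,
    decision = parse_final_answer(raw, template),
    latency_seconds = as.numeric(proc.time()[["elapsed"]] - t0)
  )
}

#' @export
backend_classify.resppheno_backend_oracle <- function(backend, prompt, payload, template) {
  t0 <- proc.time()[["elapsed"]]
  respond(backend, oracle_decision(backend$lexicon, template$task, payload), template, t0)
}

# hash -> uniform in [0, 1), deterministic per (seed, task, payload)
hash_unif <- function(...) {
  strtoi(substr(rlang::hash(list(...)), 1, 7), base = 16L) / 16^7
}

#' @export
backend_classify.resppheno_backend_noisy <- function(backend, prompt, payload, template) {
  t0 <- proc.time()[["elapsed"]]
  decision <- oracle_decision(backend$lexicon, template$task, payload)
  if (hash_unif(backend$seed, template$task, payload, "flip") < backend$flip_prob) {
    decision <- if (template$task == "phenotype") {
      others <- setdiff(phenotype_levels(), decision)
      others[1L + floor(hash_unif(backend$seed, template$task, payload, "pick") * length(others))]
    } else {
      if (decision == "YES") "NO" else "YES"
    }
  }
  respond(backend, decision, template, t0)
}

#' @export
backend_classify.resppheno_backend_cached <- function(backend, prompt, payload, template) {
  key <- rlang::hash(list(backend$label, prompt))
  path <- file.path(backend$cache_dir, paste0(key, ".json"))
  if (file.exists(path)) {
    hit <- jsonlite::read_json(path)
    return(tibble::tibble(
      raw_text = hit$raw_text,
      decision = hit$decision,
      latency_seconds = as.numeric(hit$latency_seconds)
    ))
  }
  res <- backend_classify(backend$inner, prompt, payload, template)
  bump_calls(backend)
  jsonlite::write_json(as.list(res), path, auto_unbox = TRUE, digits = NA)
  res
}

#' @export
backend_classify.resppheno_backend_ollama <- function(backend, prompt, payload, template) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    rlang::abort("the 'curl' package is required for live backends",
      class = "resppheno_backend_error"
    )
  }
  s <- backend$settings
  body <- list(
    model = s$model_name, prompt = prompt, stream = FALSE,
    options = c(
      list(temperature = s$temperature, top_p = s$top_p),
      if (!is.null(s$max_tokens)) list(num_predict = s$max_tokens)
    )
  )
  url <- paste0(sub("/$", "", s$endpoint), "/api/generate")
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(
      {
        h <- curl::new_handle(
          postfields = jsonlite::toJSON(body, auto_unbox = TRUE),
          timeout = s$timeout
        )
        curl::handle_setheaders(h, "Content-Type" = "application/json")
        resp <- curl::curl_fetch_memory(url, handle = h)
        if (resp$status_code != 200) {
          stop("HTTP status ", resp$status_code)
        }
        jsonlite::fromJSON(rawToChar(resp$content))$response
      },
      error = identity
    )
    latency <- proc.time()[["elapsed"]] - t0
    if (!inherits(out, "error")) {
      bump_calls(backend)
      return(tibble::tibble(
        raw_text = out,
        decision = parse_final_answer(out, template),
        latency_seconds = as.numeric(latency)
      ))
    }
    if (attempt > s$retries) {
      rlang::abort(
        paste0(
          "Live backend failed after ", attempt, " attempt(s): ",
          conditionMessage(out)
        ),
        class = "resppheno_backend_error"
      )
    }
  }
}
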