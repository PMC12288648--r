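#' Configuration for the synthetic EHR generator
#'
#' The generator emulates the nine eICU-style source tables with planted
#' therapy-sequence phenotypes so that every pipeline stage can be exercised
#' offline against known truth. Defaults reflect the published cohort
#' composition for ARF respiratory-support phenotypes (about 83% of
#' encounters with no qualifying therapy, 10% IMV only, and rare multi-
#' therapy sequences) and a realistic excess of irrelevant charting records
#' per encounter.
#'
#' @param n_patients number of patients to simulate.
#' @param phenotype_mix named probability vector over [phenotype_levels()];
#'   must sum to 1. Default: the published cohort frequencies.
#' @param distractor_rate mean number of irrelevant records per encounter
#'   (Poisson).
#' @param concept_bank bank of table rows to sample records from; see
#'   [default_concept_bank()].
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @param p_minor probability a patient is under 18 (their encounter is
#'   excluded by the cohort filters and flagged ineligible in the truths).
#' @param p_extra_encounter probability a patient has a second, later
#'   encounter (excluded by the first-encounter rule).
#' @param p_age_over89 probability an adult's age is the de-identification
#'   sentinel `">89"`.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_patients = 500,
                             phenotype_mix = NULL,
                             distractor_rate = 20,
                             concept_bank = default_concept_bank(),
                             seed = 1L,
                             p_minor = 0.05,
                             p_extra_encounter = 0.10,
                             p_age_over89 = 0.03) {
  if (is.null(phenotype_mix)) {
    counts <- c(
      "IMV Only" = 16736, "NIPPV Only" = 6833, "HFNI Only" = 1089,
      "NIPPV Failure" = 1466, "HFNI Failure" = 568,
      "IMV to NIPPV" = 601, "IMV to HFNI" = 186, "None" = 132222
    )
    phenotype_mix <- counts / sum(counts)
  }
  if (!setequal(names(phenotype_mix), phenotype_levels())) {
    rlang::abort("phenotype_mix must be named by the eight phenotype labels",
      class = "resppheno_config_error"
    )
  }
  if (abs(sum(phenotype_mix) - 1) > 1e-8 || any(phenotype_mix < 0)) {
    rlang::abort("phenotype_mix must be non-negative and sum to 1",
      class = "resppheno_config_error"
    )
  }
  if (distractor_rate < 0) {
    rlang::abort("distractor_rate must be >= 0", class = "resppheno_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      phenotype_mix = phenotype_mix[phenotype_levels()],
      distractor_rate = distractor_rate,
      concept_bank = concept_bank,
      seed = as.integer(seed),
      p_minor = p_minor,
      p_extra_encounter = p_extra_encounter,
      p_age_over89 = p_age_over89
    ),
    class = "generator_config"
  )
}

# integer sample without the length-1 surprise of sample()
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# n distinct integer offsets in [lo, hi]
draw_offsets <- function(n, lo, hi) {
  sample_from(lo:hi, n)
}

# Plant event indices/offsets for one encounter. `pool` is a list of bank row
# indices per category. Returns list(idx = integer, offset = integer).
#
# Geometry guarantees (needed so that rank order in a deduplicated
# description reproduces offset order): therapy records within an encounter
# always use distinct concepts; noninvasive and IMV episode windows are
# disjoint; "weaning" noninvasive records planted to exercise the interval
# rule lie strictly inside the IMV span.
plant_events <- function(phenotype, pool) {
  idx <- integer()
  off <- integer()
  add <- function(i, o) {
    idx <<- c(idx, i)
    off <<- c(off, as.integer(o))
  }

  imv_block <- function(s_lo, s_hi) {
    k <- sample_from(2:4, 1)
    start <- sample_from(s_lo:s_hi, 1)
    end <- start + sample_from(500:2500, 1)
    mids <- if (k > 2) draw_offsets(k - 2, start + 1, end - 1) else integer()
    add(sample_from(pool$IMV, k), c(start, mids, end))
    m <- sample_from(1:2, 1)
    add(sample_from(pool$medication, m), draw_offsets(m, start, end))
    c(start = start, end = end)
  }
  ni_block <- function(kind, lo, hi) {
    k <- sample_from(2:4, 1)
    i <- if (kind == "HFNI") {
      n_h <- sample_from(seq_len(min(k, length(pool$HFNI))), 1)
      c(sample_from(pool$HFNI, n_h), sample_from(pool$NIPPV, k - n_h))
    } else {
      sample_from(pool$NIPPV, k)
    }
    add(i, draw_offsets(k, lo, hi))
  }
  # sub-threshold extras that must never flip the label
  maybe_single_ni <- function(p = 0.25) {
    if (stats::runif(1) < p) add(sample_from(c(pool$NIPPV, pool$HFNI), 1), draw_offsets(1, 0, 4000))
  }
  maybe_single_imv <- function(p = 0.2) {
    if (stats::runif(1) < p) add(sample_from(pool$IMV, 1), draw_offsets(1, 0, 4000))
  }
  maybe_med <- function(p = 0.3) {
    if (stats::runif(1) < p) add(sample_from(pool$medication, 1), draw_offsets(1, 0, 4000))
  }

  switch(phenotype,
    "None" = {
      maybe_single_ni(0.25)
      if (stats::runif(1) < 0.15) { # two IMV records but no medication
        add(sample_from(pool$IMV, 2), draw_offsets(2, 0, 4000))
      } else {
        maybe_med(0.1)
      }
    },
    "IMV Only" = {
      span <- imv_block(0, 1000)
      if (stats::runif(1) < 0.3) { # weaning-trial records removed by the interval rule
        n_in <- sample_from(1:2, 1)
        add(
          sample_from(c(pool$NIPPV, pool$HFNI), n_in),
          draw_offsets(n_in, span["start"] + 1, span["end"] - 1)
        )
      }
    },
    "NIPPV Only" = {
      ni_block("NIPPV", 0, 4000)
      maybe_single_imv()
      maybe_med()
    },
    "HFNI Only" = {
      ni_block("HFNI", 0, 4000)
      maybe_single_imv()
      maybe_med()
    },
    "NIPPV Failure" = {
      ni_block("NIPPV", 0, 2000)
      imv_block(2500, 3000)
    },
    "HFNI Failure" = {
      ni_block("HFNI", 0, 2000)
      imv_block(2500, 3000)
    },
    "IMV to NIPPV" = {
      imv_block(0, 400)
      ni_block("NIPPV", 3500, 7000)
    },
    "IMV to HFNI" = {
      imv_block(0, 400)
      ni_block("HFNI", 3500, 7000)
    },
    rlang::abort(paste0("Unknown phenotype: ", phenotype),
      class = "resppheno_config_error"
    )
  )
  list(idx = idx, offset = off)
}

bank_pool <- function(bank) {
  list(
    IMV = which(bank$category == "IMV"),
    NIPPV = which(bank$category == "NIPPV"),
    HFNI = which(bank$category == "HFNI"),
    medication = which(bank$category == "medication"),
    distractor = which(bank$category == "distractor")
  )
}

bank_rows_to_records <- function(bank, idx, offset, encounter_id) {
  out <- bank[idx, c("table", all_field_columns()), drop = FALSE]
  out <- dplyr::mutate(out,
    encounter_id = encounter_id,
    offset_minutes = as.integer(offset),
    .before = 1
  )
  dplyr::select(
    out, "encounter_id", "table", "offset_minutes",
    dplyr::all_of(all_field_columns())
  )
}

#' Plant the records of one phenotype
#'
#' Emits a record tibble for one encounter that satisfies the reference
#' criteria for exactly the requested phenotype: for sequence phenotypes all
#' qualifying noninvasive offsets strictly precede (or follow) the IMV
#' episode; "None" encounters contain at most sub-threshold therapy evidence.
#' Uses the session RNG; call `set.seed()` (or use [generate_cohort()]) for
#' reproducibility.
#'
#' @param phenotype one of [phenotype_levels()].
#' @param bank concept bank, see [default_concept_bank()].
#' @param encounter_id identifier for the emitted records.
#' @param distractor_rate mean number of irrelevant records to interleave.
#' @return A record tibble.
#' @export
plant_phenotype <- function(phenotype, bank = default_concept_bank(),
                            encounter_id = "e1", distractor_rate = 0) {
  if (!phenotype %in% phenotype_levels()) {
    rlang::abort(paste0("Unknown phenotype: ", phenotype),
      class = "resppheno_config_error"
    )
  }
  pool <- bank_pool(bank)
  ev <- plant_events(phenotype, pool)
  n_d <- stats::rpois(1, distractor_rate)
  if (n_d > 0) {
    ev$idx <- c(ev$idx, sample_from(pool$distractor, n_d, replace = TRUE))
    ev$offset <- c(ev$offset, sample_from(-300:8000, n_d, replace = TRUE))
  }
  bank_rows_to_records(bank, ev$idx, ev$offset, encounter_id)
}

#' Generate a synthetic cohort with planted phenotypes
#'
#' Simulates patients, encounters and timestamped records across the nine
#' source tables. Each patient's first encounter carries a phenotype drawn
#' from `phenotype_mix`; a small fraction of patients are minors or have
#' additional later encounters so that the cohort filters are exercised
#' (those encounters are flagged `eligible = FALSE` in the truths and are
#' not covered by the 100%-recovery guarantee). Identical seeds give
#' identical output.
#'
#' @param config a [generator_config()].
#' @return A list of class `ehr_cohort` with elements `records` (record
#'   tibble), `encounters` (`encounter_id`, `patient_id`, `age_years`,
#'   `admit_order`), `truths` (`encounter_id`, `phenotype`, `eligible`,
#'   `episode_offsets` list column of planted offsets per concept category)
#'   and `lexicon` (the [relevance_lexicon()] implied by the bank).
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 20, seed = 42))
#' dplyr::count(cohort$truths, phenotype)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()),
    add = TRUE
  )
  set.seed(config$seed)

  bank <- config$concept_bank
  pool <- bank_pool(bank)
  lex <- lexicon_from_bank(bank)
  mix <- config$phenotype_mix

  enc_ids <- character()
  pat_ids <- character()
  ages <- character()
  orders <- integer()
  phenos <- character()
  eligible <- logical()

  rec_idx <- vector("list", 0)
  rec_off <- vector("list", 0)
  rec_enc <- character()
  ep_offsets <- vector("list", 0)

  n <- config$n_patients
  for (p in seq_len(n)) {
    pid <- sprintf("P%05d", p)
    minor <- stats::runif(1) < config$p_minor
    age <- if (minor) {
      as.character(sample_from(1:17, 1))
    } else if (stats::runif(1) < config$p_age_over89) {
      ">89"
    } else {
      as.character(sample_from(18:89, 1))
    }
    n_enc <- 1L + (stats::runif(1) < config$p_extra_encounter)
    for (k in seq_len(n_enc)) {
      eid <- sprintf("%s-%d", pid, k)
      ph <- sample_from(phenotype_levels(), 1)
      # first adult encounter uses the configured mix; excluded encounters
      # draw uniformly so filter bugs surface loudly in recovery tests
      if (k == 1L) ph <- sample(phenotype_levels(), 1, prob = mix)
      ev <- plant_events(ph, pool)
      n_d <- stats::rpois(1, config$distractor_rate)
      if (n_d > 0) {
        ev$idx <- c(ev$idx, sample_from(pool$distractor, n_d, replace = TRUE))
        ev$offset <- c(ev$offset, sample_from(-300:8000, n_d, replace = TRUE))
      }
      enc_ids <- c(enc_ids, eid)
      pat_ids <- c(pat_ids, pid)
      ages <- c(ages, age)
      orders <- c(orders, k)
      phenos <- c(phenos, ph)
      eligible <- c(eligible, !minor && k == 1L)
      rec_idx[[length(rec_idx) + 1]] <- ev$idx
      rec_off[[length(rec_off) + 1]] <- ev$offset
      rec_enc <- c(rec_enc, eid)
      ep_offsets[[length(ep_offsets) + 1]] <- split(
        ev$offset,
        bank$category[ev$idx]
      )
    }
  }

  counts <- lengths(rec_idx)
  records <- bank_rows_to_records(
    bank,
    unlist(rec_idx, use.names = FALSE),
    unlist(rec_off, use.names = FALSE),
    rep(rec_enc, counts)
  )
  encounters <- tibble::tibble(
    encounter_id = enc_ids, patient_id = pat_ids,
    age_years = ages, admit_order = orders
  )
  truths <- tibble::tibble(
    encounter_id = enc_ids, phenotype = phenos,
    eligible = eligible, episode_offsets = ep_offsets
  )
  structure(
    list(records = records, encounters = encounters, truths = truths, lexicon = lex),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  cat("  encounters:", nrow(x$encounters), " records:", nrow(x$records), "\n")
  tab <- table(x$truths$phenotype[x$truths$eligible])
  cat("  eligible-encounter phenotypes:\n")
  for (nm in names(tab)) cat(sprintf("    %-14s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Balanced synthetic concept truths for stress-testing selection
#'
#' Builds `n_per_class` synthetic therapy-relevant concept strings and the
#' same number of distractors, with the matching [relevance_lexicon()], for
#' measuring concept-selection accuracy under backend noise at scale.
#'
#' @param n_per_class number of concepts per class.
#' @return list with `lexicon` and `concepts` (tibble of `concept`,
#'   `relevant` logical truth).
#' @export
synthetic_concept_truths <- function(n_per_class = 5000) {
  rel <- sprintf("Source = Nurse Charting; Concept = O2 Admin Device: Support Device %05d", seq_len(n_per_class))
  dis <- sprintf("Source = Nurse Charting; Concept = Routine Observation: Value %05d", seq_len(n_per_class))
  list(
    lexicon = relevance_lexicon(
      imv = character(), nippv = rel, hfni = character(),
      medications = character(), distractors = dis
    ),
    concepts = tibble::tibble(
      concept = c(rel, dis),
      relevant = rep(c(TRUE, FALSE), each = n_per_class)
    )
  )
}
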