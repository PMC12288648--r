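lex <- fixture_lexicon

test_that("therapy criteria: IMV needs two records plus a medication", {
  ep <- detect_therapies(micro_records(IMV = c(50, 300), medication = 60), lex)
  expect_equal(ep$therapy, "IMV")
  expect_equal(ep$start_offset, 50L)
  expect_equal(ep$end_offset, 300L)
  expect_equal(ep$supporting_record_count, 2L)

  # medication co-requirement unmet
  ep <- detect_therapies(micro_records(IMV = c(50, 300)), lex)
  expect_equal(nrow(ep), 0)
  # a lone medication record is not an episode either
  ep <- detect_therapies(micro_records(medication = 60), lex)
  expect_equal(nrow(ep), 0)
})

test_that("therapy criteria: noninvasive episodes and the HFNI reading", {
  ep <- detect_therapies(micro_records(NIPPV = c(10, 400)), lex)
  expect_equal(ep$therapy, "NIPPV")

  # two noninvasive records of which one indicates HFNI -> HFNI
  ep <- detect_therapies(micro_records(NIPPV = 10, HFNI = 400), lex)
  expect_equal(ep$therapy, "HFNI")
  expect_equal(ep$start_offset, 10L)
  expect_equal(ep$end_offset, 400L)
  expect_equal(ep$supporting_record_count, 2L)

  # one record is never enough
  ep <- detect_therapies(micro_records(HFNI = 10), lex)
  expect_equal(nrow(ep), 0)
})

test_that("interval rule removes in-span noninvasive records and reassesses", {
  recs <- micro_records(IMV = c(50, 300), medication = 60, NIPPV = c(100, 200))
  out <- apply_imv_interval_rule(recs, lex)
  cat <- resppheno:::concept_category(build_concepts(out)$concept, lex)
  expect_equal(sum(cat == "NIPPV", na.rm = TRUE), 0)
  expect_equal(phenotype_encounter(recs, lex), "IMV Only")

  # outside the span they are retained and order decides the sequence
  recs <- micro_records(IMV = c(50, 300), medication = 60, NIPPV = c(10, 20))
  out <- apply_imv_interval_rule(recs, lex)
  expect_equal(nrow(out), nrow(recs))
  expect_equal(phenotype_encounter(recs, lex), "NIPPV Failure")

  # no IMV episode -> identity
  recs <- micro_records(NIPPV = c(100, 200), IMV = 150)
  expect_equal(apply_imv_interval_rule(recs, lex), recs)

  # idempotence
  recs <- micro_records(IMV = c(0, 1000), medication = 5, HFNI = c(100, 900), NIPPV = 2000)
  once <- apply_imv_interval_rule(recs, lex)
  expect_equal(apply_imv_interval_rule(once, lex), once)
})

test_that("episode combinations map onto the eight classes, ties refuse to guess", {
  ep <- function(therapy, start) {
    tibble::tibble(
      therapy = therapy, start_offset = start,
      end_offset = start + 10L, supporting_record_count = 2L
    )
  }
  expect_equal(classify_phenotype(ep(character(), integer())), "None")
  expect_equal(classify_phenotype(ep("IMV", 10L)), "IMV Only")
  expect_equal(classify_phenotype(ep("HFNI", 10L)), "HFNI Only")
  expect_equal(
    classify_phenotype(dplyr::bind_rows(ep("NIPPV", 10L), ep("IMV", 500L))),
    "NIPPV Failure"
  )
  expect_equal(
    classify_phenotype(dplyr::bind_rows(ep("IMV", 10L), ep("HFNI", 900L))),
    "IMV to HFNI"
  )
  expect_error(
    classify_phenotype(dplyr::bind_rows(ep("IMV", 10L), ep("NIPPV", 10L))),
    class = "resppheno_unclassifiable"
  )
  expect_error(
    classify_phenotype(dplyr::bind_rows(ep("IMV", 1L), ep("NIPPV", 2L), ep("HFNI", 3L))),
    class = "resppheno_unclassifiable"
  )
})

test_that("cohort filters: first encounter per patient, adults only", {
  enc <- tibble::tibble(
    encounter_id = c("a1", "a2", "a3", "b1"),
    patient_id = c("A", "A", "A", "B"),
    age_years = c("40", "40", "40", "17"),
    admit_order = c(2L, 1L, 3L, 1L)
  )
  first <- select_first_encounters(enc)
  expect_equal(sort(first$encounter_id), c("a2", "b1"))

  dup <- enc
  dup$admit_order <- c(1L, 1L, 3L, 1L)
  expect_error(select_first_encounters(dup), class = "resppheno_ambiguity_error")

  adults <- filter_adults(tibble::tibble(
    encounter_id = c("x", "y", "z", "w"),
    patient_id = c("X", "Y", "Z", "W"),
    age_years = c("17", "18", ">89", "40"),
    admit_order = 1L
  ))
  expect_equal(sort(adults$encounter_id), c("w", "y", "z"))

  expect_warning(
    bad <- filter_adults(tibble::tibble(
      encounter_id = "q", patient_id = "Q",
      age_years = "unknown", admit_order = 1L
    )),
    "unparseable"
  )
  expect_equal(nrow(bad), 0)
})

test_that("first-encounter count equals the number of distinct patients", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    enc <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:15), n, replace = TRUE)
    ) |>
      dplyr::mutate(
        admit_order = as.integer(stats::ave(seq_len(n), patient_id, FUN = seq_along)),
        encounter_id = paste0(patient_id, "-", admit_order),
        age_years = "50"
      )
    expect_equal(
      nrow(select_first_encounters(enc)),
      dplyr::n_distinct(enc$patient_id)
    )
  }
})

test_that("labels are invariant to record order and distractor load", {
  set.seed(5)
  cohort <- generate_cohort(generator_config(n_patients = 25, seed = 17, distractor_rate = 5))
  ids <- unique(cohort$records$encounter_id)
  for (id in ids[1:10]) {
    recs <- cohort$records[cohort$records$encounter_id == id, ]
    base <- phenotype_encounter(recs, cohort$lexicon)
    shuffled <- recs[sample.int(nrow(recs)), ]
    expect_equal(phenotype_encounter(shuffled, cohort$lexicon), base)
    noisy <- dplyr::bind_rows(
      recs,
      dplyr::filter(
        build_concepts(plant_phenotype("None", fixture_bank, encounter_id = id, distractor_rate = 12)),
        !is.na(concept) & concept %in% fixture_lexicon$distractors
      ) |> dplyr::select(-concept, -source_table)
    )
    expect_equal(phenotype_encounter(noisy, cohort$lexicon), base)
  }
})

test_that("encounters with only distractor records are labeled None", {
  recs <- bank_rec("distractor", 1:4, c(-10, 5, 100, 4000))
  expect_equal(phenotype_encounter(recs, lex), "None")
})
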