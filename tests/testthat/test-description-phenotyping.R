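lex <- fixture_lexicon
selected_all <- relevant_concepts(lex)

test_that("descriptions rank distinct concepts by first occurrence", {
  # two concepts first seen at offsets 30 and 10: the earlier one is rank 1
  recs <- dplyr::bind_rows(
    bank_rec("NIPPV", 1, 30),
    bank_rec("NIPPV", 2, 10)
  )
  d <- build_description(recs, selected_all)
  lines <- strsplit(d, "\n")[[1]]
  c1 <- fixture_bank$concept[fixture_bank$category == "NIPPV"][1]
  c2 <- fixture_bank$concept[fixture_bank$category == "NIPPV"][2]
  expect_equal(lines, c(paste0("1: ", c2), paste0("2: ", c1)))

  # a duplicated concept appears once, ranked by its first offset
  recs <- dplyr::bind_rows(
    bank_rec("NIPPV", 1, 400),
    bank_rec("NIPPV", 2, 50),
    bank_rec("NIPPV", 1, 10)
  )
  d <- build_description(recs, selected_all)
  expect_equal(strsplit(d, "\n")[[1]], c(paste0("1: ", c1), paste0("2: ", c2)))

  # single concept
  recs <- bank_rec("medication", 1, 5)
  expect_equal(
    build_description(recs, selected_all),
    paste0("1: ", fixture_bank$concept[fixture_bank$category == "medication"][1])
  )

  # unselected concepts are dropped; nothing selected -> empty description
  recs <- bank_rec("distractor", 1:3, c(1, 2, 3))
  expect_equal(build_description(recs, selected_all), "")

  # first-occurrence ties break lexicographically for determinism
  recs <- dplyr::bind_rows(bank_rec("NIPPV", 1, 100), bank_rec("NIPPV", 2, 100))
  lines <- strsplit(build_description(recs, selected_all), "\n")[[1]]
  expect_equal(sub("^[0-9]+: ", "", lines), sort(c(c1, c2)))
})

test_that("descriptions contain only ranks and concept text", {
  cohort <- generate_cohort(generator_config(n_patients = 30, seed = 41))
  descs <- build_descriptions(cohort$records, selected_all, cohort$encounters)
  expect_equal(nrow(descs), nrow(cohort$encounters))
  nonempty <- descs$description[nzchar(descs$description)]
  expect_false(any(stringr::str_detect(nonempty, stringr::fixed(cohort$encounters$encounter_id[1]))))
  expect_true(all(stringr::str_detect(
    unlist(strsplit(nonempty, "\n")), "^[0-9]+: Source = "
  )))
  # ranks are 1..n with no gaps
  ranks <- lapply(strsplit(nonempty, "\n"), function(l) as.integer(sub(":.*", "", l)))
  expect_true(all(vapply(ranks, function(r) identical(r, seq_along(r)), logical(1))))
})

test_that("unique descriptions are classified once and mapped back", {
  recs <- dplyr::bind_rows(
    micro_records(NIPPV = c(10, 20), encounter_id = "e1"),
    micro_records(NIPPV = c(10, 20), encounter_id = "e2"), # same description as e1
    micro_records(IMV = c(5, 500), medication = 50, encounter_id = "e3")
  )
  enc <- tibble::tibble(
    encounter_id = c("e1", "e2", "e3"), patient_id = c("p1", "p2", "p3"),
    age_years = "50", admit_order = 1L
  )
  b <- backend_oracle(lex)
  res <- apply_algorithm(recs, enc, selected_all, b, fixture_templates$phenotype)
  expect_equal(nrow(res$encounter_labels), 3)
  expect_equal(res$n_backend_calls, 2) # 3 encounters, 2 unique descriptions
  expect_equal(backend_calls(b), 2L)
  labels <- tibble::deframe(res$encounter_labels)
  expect_equal(unname(labels[c("e1", "e2", "e3")]), c("NIPPV Only", "NIPPV Only", "IMV Only"))

  # round-trip: grouping encounter labels by description recovers desc_labels
  joined <- dplyr::inner_join(res$descriptions, res$encounter_labels, by = "encounter_id")
  regrouped <- dplyr::distinct(joined, description, phenotype)
  expect_equal(
    dplyr::arrange(regrouped, description),
    dplyr::arrange(dplyr::select(res$desc_labels, description, phenotype), description)
  )
})

test_that("empty descriptions are labeled None without a backend call", {
  b <- backend_oracle(lex)
  out <- phenotype_descriptions(c("", ""), b, fixture_templates$phenotype)
  expect_equal(out$phenotype, "None")
  expect_equal(backend_calls(b), 0L)
})

test_that("encounter order does not affect the mapped labels", {
  cohort <- generate_cohort(generator_config(n_patients = 40, seed = 77))
  kept <- filter_adults(select_first_encounters(cohort$encounters))
  recs <- cohort$records[cohort$records$encounter_id %in% kept$encounter_id, ]
  res1 <- apply_algorithm(
    recs, kept, selected_all,
    backend_oracle(lex), fixture_templates$phenotype
  )
  perm <- kept[sample.int(nrow(kept)), ]
  res2 <- apply_algorithm(
    recs[sample.int(nrow(recs)), ], perm, selected_all,
    backend_oracle(lex), fixture_templates$phenotype
  )
  expect_equal(
    dplyr::arrange(res1$encounter_labels, encounter_id),
    dplyr::arrange(res2$encounter_labels, encounter_id)
  )
  expect_lte(nrow(res1$desc_labels), nrow(kept))
})

test_that("missing description mappings are integrity errors", {
  desc_labels <- tibble::tibble(
    description = "1: x", phenotype = "None", latency_seconds = 0
  )
  enc_desc <- tibble::tibble(encounter_id = c("e1", "e2"), description = c("1: x", "1: y"))
  expect_error(
    map_to_encounters(desc_labels, enc_desc),
    class = "resppheno_integrity_error"
  )
})
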