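test_that("assembled prompts contain the payload once and questions in order", {
  tpl <- fixture_templates$therapy
  payload <- "Source = Medication; Concept = LOPRESSOR"
  prompt <- assemble_prompt(tpl, payload)
  expect_equal(
    lengths(regmatches(prompt, gregexpr(payload, prompt, fixed = TRUE))), 1L
  )
  pos <- vapply(
    c(tpl$cot_questions, tpl$final_question),
    function(q) regexpr(q, prompt, fixed = TRUE)[[1]],
    numeric(1)
  )
  expect_true(all(diff(pos) > 0)) # in order, final question last
  expect_gt(min(pos), regexpr(payload, prompt, fixed = TRUE)[[1]])

  # no chain-of-thought questions: preamble + final question only
  bare <- prompt_template(
    task = "concept-therapy", preamble = "Concept: {payload}",
    final_question = "FINAL ANSWER (YES or NO):", answer_vocabulary = c("YES", "NO")
  )
  expect_equal(
    assemble_prompt(bare, "x"),
    "Concept: x\n\nFINAL ANSWER (YES or NO):"
  )

  # prompt length grows by exactly the payload length
  expect_equal(
    nchar(assemble_prompt(tpl, payload)) - nchar(assemble_prompt(tpl, "")),
    nchar(payload)
  )
})

test_that("unresolved placeholders are template errors", {
  tpl <- prompt_template(
    task = "concept-therapy", preamble = "{definitions}\n{payload}",
    final_question = "FINAL ANSWER:", answer_vocabulary = c("YES", "NO")
  )
  expect_error(assemble_prompt(tpl, "x"), class = "resppheno_template_error")
  expect_no_error(assemble_prompt(tpl, "x", fields = list(definitions = "defs")))
  expect_error(
    prompt_template(task = "t", preamble = "p", final_question = "", answer_vocabulary = "YES"),
    class = "resppheno_template_error"
  )
})

test_that("final answers parse case-insensitively, last token wins", {
  tpl <- fixture_templates$therapy
  expect_equal(parse_final_answer("...Final answer: YES", tpl), "YES")
  expect_equal(parse_final_answer("...final answer: no.", tpl), "NO")
  expect_equal(parse_final_answer("I cannot determine this.", tpl), "UNPARSEABLE")
  # reasoning mentions both tokens after the marker: last one wins
  expect_equal(
    parse_final_answer("FINAL ANSWER: maybe YES but really NO", tpl), "NO"
  )
  # only the segment after the LAST marker occurrence counts
  expect_equal(
    parse_final_answer("FINAL ANSWER: YES ... FINAL ANSWER: NO", tpl), "NO"
  )
  ptpl <- fixture_templates$phenotype
  expect_equal(
    parse_final_answer("FINAL PHENOTYPE: imv to nippv", ptpl), "IMV to NIPPV"
  )
  expect_equal(parse_final_answer("FINAL PHENOTYPE: unsure", ptpl), "UNPARSEABLE")
})

test_that("oracle answers from the lexicon and parsing round-trips", {
  b <- backend_oracle(fixture_lexicon)
  hfni_concept <- "Source = Nurse Charting; Concept = O2 Admin Device: Hi Flow NC"
  res <- backend_classify(
    b, assemble_prompt(fixture_templates$therapy, hfni_concept),
    hfni_concept, fixture_templates$therapy
  )
  expect_equal(res$decision, "YES")
  expect_gte(res$latency_seconds, 0)

  distractor <- fixture_lexicon$distractors[1]
  res <- backend_classify(
    b, assemble_prompt(fixture_templates$therapy, distractor),
    distractor, fixture_templates$therapy
  )
  expect_equal(res$decision, "NO")

  # round-trip: every phenotype vocabulary token survives compose -> parse
  ptpl <- fixture_templates$phenotype
  for (label in phenotype_levels()) {
    raw <- resppheno:::oracle_raw_text(label, ptpl)
    expect_equal(parse_final_answer(raw, ptpl), label)
  }
  expect_equal(backend_calls(b), 2L)
})

test_that("noisy backend: flip 0 is the oracle, flip 1 its complement", {
  tpl <- fixture_templates$therapy
  payloads <- c(fixture_lexicon$therapy$IMV[1:3], fixture_lexicon$distractors[1:3])
  o <- backend_oracle(fixture_lexicon)
  b0 <- backend_noisy(fixture_lexicon, 0, seed = 3)
  b1 <- backend_noisy(fixture_lexicon, 1, seed = 3)
  for (p in payloads) {
    prompt <- assemble_prompt(tpl, p)
    d_o <- backend_classify(o, prompt, p, tpl)$decision
    expect_equal(backend_classify(b0, prompt, p, tpl)$decision, d_o)
    expect_equal(
      backend_classify(b1, prompt, p, tpl)$decision,
      if (d_o == "YES") "NO" else "YES"
    )
  }
  # deterministic per payload: rerun gives identical decisions
  bn <- backend_noisy(fixture_lexicon, 0.5, seed = 9)
  d1 <- vapply(payloads, function(p) backend_classify(bn, p, p, tpl)$decision, character(1))
  d2 <- vapply(payloads, function(p) backend_classify(bn, p, p, tpl)$decision, character(1))
  expect_equal(d1, d2)
})

test_that("response cache serves repeats without new backend calls", {
  cache <- withr::local_tempdir()
  inner <- backend_oracle(fixture_lexicon)
  b <- backend_cached(inner, cache)
  tpl <- fixture_templates$therapy
  payloads <- c(fixture_lexicon$therapy$NIPPV[1:4], fixture_lexicon$distractors[1:4])
  first <- vapply(payloads, function(p) {
    backend_classify(b, assemble_prompt(tpl, p), p, tpl)$decision
  }, character(1))
  expect_equal(backend_calls(inner), length(payloads))

  inner2 <- backend_oracle(fixture_lexicon)
  b2 <- backend_cached(inner2, cache)
  second <- vapply(payloads, function(p) {
    backend_classify(b2, assemble_prompt(tpl, p), p, tpl)$decision
  }, character(1))
  expect_equal(backend_calls(inner2), 0L) # all served from cache
  expect_equal(second, first)
})

test_that("decoding settings validate their ranges", {
  s <- decoding_settings("mistral-small")
  expect_equal(s$temperature, 0.0)
  expect_equal(s$top_p, 0.99)
  expect_error(decoding_settings("m", temperature = -1), class = "resppheno_config_error")
  expect_error(decoding_settings("m", top_p = 0), class = "resppheno_config_error")
  expect_error(backend_noisy(fixture_lexicon, 1.5), class = "resppheno_config_error")
})

test_that("unreachable live endpoint is a backend error after retries", {
  skip_if_not_installed("curl")
  b <- backend_ollama(decoding_settings(
    "missing-model",
    endpoint = "http://127.0.0.1:1", retries = 0L, timeout = 1
  ))
  tpl <- fixture_templates$therapy
  expect_error(
    backend_classify(b, "prompt", "payload", tpl),
    class = "resppheno_backend_error"
  )
  expect_equal(backend_calls(b), 0L)
})
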