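test_that("generation is deterministic given (seed, report_index)", {
  cfg <- generator_config(seed = 5, typo_rate = 0)
  a <- generate_report(cfg, 3)
  b <- generate_report(cfg, 3)
  expect_identical(a, b)
  # typo injection is part of the same deterministic stream
  cfgt <- generator_config(seed = 5, typo_rate = 0.1)
  expect_identical(generate_report(cfgt, 3), generate_report(cfgt, 3))
  # different seed or index changes the output
  expect_false(identical(a, generate_report(generator_config(seed = 6,
                                                             typo_rate = 0), 3)))
  expect_false(identical(a, generate_report(cfg, 4)))
})

test_that("every generated fact validates against the default schema", {
  sch <- default_schema()
  co <- generate_corpus(generator_config(seed = 21, n_reports = 12,
                                         facts_per_report_mean = 25,
                                         typo_rate = 0.05))
  for (ar in co) {
    nt <- nrow(ar$report$tokens)
    expect_gt(length(ar$facts), 0)
    for (f in ar$facts) {
      expect_identical(validate_fact(f, sch, nt), character(0))
    }
  }
})

test_that("re-tokenizing generated text reproduces the gold token stream", {
  co <- generate_corpus(generator_config(seed = 31, n_reports = 6,
                                         typo_rate = 0.08,
                                         facts_per_report_mean = 20))
  for (ar in co) {
    expect_identical(tokenize(ar$report$text), ar$report$tokens)
  }
})

test_that("anchor text matches a lexicon entry (gold-consistency)", {
  bank <- default_template_bank()
  lex_strings <- unlist(lapply(bank$lex, function(entries) {
    vapply(entries, paste, character(1), collapse = " ")
  }), use.names = FALSE)
  co <- generate_corpus(generator_config(seed = 41, n_reports = 4,
                                         typo_rate = 0,
                                         facts_per_report_mean = 20))
  for (ar in co) {
    toks <- ar$report$tokens$text
    for (f in ar$facts) {
      anchor_txt <- paste(toks[(f$anchor_span[1] + 1):f$anchor_span[2]],
                          collapse = " ")
      expect_true(anchor_txt %in% lex_strings || anchor_txt %in% tolower(lex_strings))
    }
  }
})

test_that("forced negation attaches a negation modifier to every finding fact", {
  cfg <- generator_config(seed = 8, n_reports = 3, negation_rate = 1,
                          facts_per_report_mean = 15,
                          fact_type_weights = c(finding_observed = 1))
  for (ar in generate_corpus(cfg)) {
    for (f in ar$facts) {
      expect_identical(f$fact_type, "finding_observed")
      expect_true("negation" %in% vapply(f$modifiers, `[[`, character(1),
                                         "slot"))
    }
  }
})

test_that("conjunction sentences yield same-type facts with shared span, distinct anchors", {
  cfg <- generator_config(seed = 13, n_reports = 2, conjunction_prob = 1,
                          facts_per_report_mean = 12,
                          fact_type_weights = c(anatomic_region_property = 1))
  saw_conjunction <- FALSE
  for (ar in generate_corpus(cfg)) {
    spans <- vapply(ar$facts, function(f) paste(f$fact_span, collapse = ":"),
                    character(1))
    for (sp in unique(spans[duplicated(spans)])) {
      group <- ar$facts[spans == sp]
      if (length(group) >= 2) {
        saw_conjunction <- TRUE
        anchors <- vapply(group, function(f) paste(f$anchor_span,
                                                   collapse = ":"),
                          character(1))
        expect_identical(anyDuplicated(anchors), 0L)
        expect_true(all(vapply(group, `[[`, character(1), "fact_type") ==
                          "anatomic_region_property"))
      }
    }
  }
  expect_true(saw_conjunction)
})

test_that("realized fact-type proportions converge to the configured weights", {
  w <- c(finding_observed = 0.6, had_procedure = 0.25, clinical_history = 0.15)
  cfg <- generator_config(seed = 17, n_reports = 40, fact_type_weights = w,
                          facts_per_report_mean = 25, conjunction_prob = 0,
                          fact_type_caps = list())
  co <- generate_corpus(cfg)
  types <- unlist(lapply(co, function(ar) {
    vapply(ar$facts, `[[`, character(1), "fact_type")
  }))
  n <- length(types)
  for (ty in names(w)) {
    observed <- sum(types == ty)
    expected <- n * w[[ty]]
    sigma <- sqrt(n * w[[ty]] * (1 - w[[ty]]))
    expect_lt(abs(observed - expected), 3 * sigma + 1)
  }
})

test_that("fact-type caps drive the rare class below 10 in a 120-report corpus", {
  cfg <- generator_config(seed = 19, n_reports = 120,
                          facts_per_report_mean = 10)
  co <- generate_corpus(cfg)
  types <- unlist(lapply(co, function(ar) {
    vapply(ar$facts, `[[`, character(1), "fact_type")
  }))
  expect_lt(sum(types == "lab_result"), 10)
  expect_gt(sum(types == "finding_observed"), 300)
})

test_that("corpus-level knobs: exact fact totals and header-free reports", {
  cfg <- generator_config(seed = 23, n_reports = 10, section_header_prob = 0,
                          facts_per_report_mean = 8)
  co <- generate_corpus(cfg, n_facts_total = 95)
  expect_identical(corpus_stats(co)$n_facts, 95L)
  expect_false(any(grepl(":", unlist(lapply(co, function(ar)
    ar$report$tokens$text)), fixed = TRUE)))
  expect_error(generate_corpus(cfg, n_facts_total = 5), "n_facts_total")
})

test_that("a weighted type without templates raises a configuration error", {
  cfg <- generator_config(seed = 1, fact_type_weights = c(mystery_fact = 1))
  expect_error(generate_report(cfg, 1), "no templates")
})
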