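test_that("token_label_sets expands the three reporting families", {
  sch <- tiny_schema()
  f1 <- rf_fact("finding_observed", c(0, 4), c(1, 2),
                modifiers = list(negation = c(1, 2)))
  expect_setequal(token_label_sets(list(f1), sch, "fact"),
                  paste0(0:3, "|finding_observed"))
  expect_identical(token_label_sets(list(f1), sch, "anchor"), "1|finding")
  expect_setequal(token_label_sets(list(f1), sch, "all"),
                  c("1|finding", "1|finding_observed:negation"))
  # overlapping same-type facts collapse per token (set semantics)
  f2 <- rf_fact("finding_observed", c(2, 6), c(3, 4))
  fam <- token_label_sets(list(f1, f2), sch, "fact")
  expect_identical(sum(fam == "2|finding_observed"), 1L)
  expect_setequal(fam, paste0(0:5, "|finding_observed"))
})

test_that("micro_prf matches worked examples and the brute-force oracle", {
  m <- micro_prf(c("0|a", "1|a"), c("1|a", "2|a"))
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 1L, 1L))
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))
  # identity on nonempty sets
  m2 <- micro_prf(c("0|a", "3|b"), c("0|a", "3|b"))
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(1, 1, 1))
  # empty prediction: zero-denominator convention
  m3 <- micro_prf(c("0|a"), character(0))
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))
  set.seed(64)
  labs <- as.vector(outer(0:5, c("a", "b"), paste, sep = "|"))
  for (i in 1:300) {
    g <- sample(labs, sample(0:8, 1))
    p <- sample(labs, sample(0:8, 1))
    ours <- micro_prf(g, p)
    ref <- oracle_micro_prf(g, p)
    expect_equal(ours[c("tp", "fp", "fn")],
                 lapply(ref[c("tp", "fp", "fn")], as.integer))
    expect_equal(ours$f1, ref$f1)
    # harmonic-mean bound
    expect_gte(ours$f1, min(ours$precision, ours$recall) - 1e-12)
    expect_lte(ours$f1, max(ours$precision, ours$recall) + 1e-12)
  }
})

test_that("oracle predictions evaluate to perfect scores; empty ones to zero", {
  sch <- default_schema()
  co <- generate_corpus(generator_config(seed = 91, n_reports = 4,
                                         facts_per_report_mean = 6))
  fake_model <- structure(list(schema = sch), class = "rf_extractor")
  gold_as_pred <- lapply(co, `[[`, "facts")
  ev <- evaluate_extractor(fake_model, co, provider = NULL,
                           predictions = gold_as_pred)
  expect_equal(ev$fact_span$f1, 1)
  expect_equal(ev$anchor$f1, 1)
  expect_equal(ev$all_spans$f1, 1)
  ev0 <- evaluate_extractor(fake_model, co, provider = NULL,
                            predictions = rep(list(list()), length(co)))
  expect_equal(ev0$fact_span$f1, 0)
  expect_equal(ev0$all_spans$recall, 0)
})

test_that("micro counts equal the sum of per-class counts in every family", {
  sch <- default_schema()
  co <- generate_corpus(generator_config(seed = 92, n_reports = 5,
                                         facts_per_report_mean = 8))
  # perturbed predictions: drop some facts, keep others
  preds <- lapply(co, function(ar) {
    keep <- ar$facts[seq_along(ar$facts) %% 2 == 1]
  })
  fake_model <- structure(list(schema = sch), class = "rf_extractor")
  ev <- evaluate_extractor(fake_model, co, provider = NULL,
                           predictions = preds)
  for (fam in c("fact", "anchor", "all")) {
    keys <- grep(paste0("^", fam, "/"), names(ev$per_class), value = TRUE)
    micro <- switch(fam, fact = ev$fact_span, anchor = ev$anchor,
                    all = ev$all_spans)
    expect_identical(sum(vapply(ev$per_class[keys], `[[`, integer(1), "tp")),
                     micro$tp)
    expect_identical(sum(vapply(ev$per_class[keys], `[[`, integer(1), "fn")),
                     micro$fn)
    expect_identical(sum(vapply(ev$per_class[keys], `[[`, integer(1), "fp")),
                     micro$fp)
  }
})
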