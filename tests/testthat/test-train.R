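test_that("early stopping halts exactly patience epochs after the peak", {
  # scripted validation trace peaking at epoch 5, patience 3 -> stops after 8
  trace <- c(0.1, 0.3, 0.5, 0.6, 0.9, 0.7, 0.8, 0.85, 0.4, 0.2)
  calls <- 0
  fit <- radfacts:::fit_with_early_stopping(
    "demo", max_epochs = 10, patience = 3,
    run_epoch = function(epoch) { calls <<- calls + 1; 1 / epoch },
    val_metric = local({ i <- 0; function() { i <<- i + 1; trace[i] } }),
    snapshot = function() list(at = calls))
  expect_identical(calls, 8)
  expect_identical(fit$best_epoch, 5L)
  expect_identical(fit$best_state$at, 5)
  expect_equal(fit$best_metric, 0.9)
  expect_identical(nrow(fit$history), 8L)
  # monotone improvement runs to max_epochs
  fit2 <- radfacts:::fit_with_early_stopping(
    "demo", max_epochs = 4, patience = 3,
    run_epoch = function(epoch) 0,
    val_metric = local({ i <- 0; function() { i <<- i + 1; i } }),
    snapshot = function() NULL)
  expect_identical(nrow(fit2$history), 4L)
  expect_identical(fit2$best_epoch, 4L)
  # non-finite loss aborts with a diagnostic
  expect_error(radfacts:::fit_with_early_stopping(
    "demo", 3, 3, function(e) NaN, function() 0, function() NULL),
    "non-finite loss")
})

# one small shared training run (kept tiny; the scaled experiment lives in
# the acceptance suite)
small_train_fixture <- local({
  env <- new.env(parent = emptyenv())
  function() {
    if (is.null(env$model)) {
      env$schema <- default_schema()
      env$corpus <- generate_corpus(generator_config(
        seed = 81, n_reports = 12, facts_per_report_mean = 8, typo_rate = 0))
      emb <- train_domain_embeddings(
        env$corpus, embedding_config(dim = 48, epochs = 3, seed = 3))
      env$provider <- embedding_provider(emb)
      env$config <- train_config(seed = 2, max_epochs = 3, patience = 3,
                                 hidden1 = 16, hidden2 = 12,
                                 learning_rate = 5e-3)
      env$model <- train_extractor(env$corpus, env$schema, env$provider,
                                   env$config)
    }
    env
  }
})

test_that("training produces a history consistent with its early-stop contract", {
  env <- small_train_fixture()
  h <- env$model$history
  expect_true(all(c("stage", "epoch", "train_loss", "val_metric") %in%
                    names(h)))
  best <- attr(h, "best_epoch")
  for (st in c("stage1", "stage2")) {
    hs <- h[h$stage == st, ]
    expect_identical(best[[st]], hs$epoch[which.max(hs$val_metric)])
    # stopped at patience after best, or at max_epochs
    expect_true(nrow(hs) == env$config$max_epochs ||
                  nrow(hs) == best[[st]] + env$config$patience)
  }
  expect_setequal(c(env$model$splits$train, env$model$splits$val,
                    env$model$splits$test),
                  vapply(env$corpus, function(a) a$report$report_id,
                         character(1)))
})

test_that("training is reproducible under a fixed seed", {
  env <- small_train_fixture()
  m2 <- train_extractor(env$corpus, env$schema, env$provider, env$config)
  expect_equal(env$model$history$train_loss, m2$history$train_loss)
  expect_equal(env$model$history$val_metric, m2$history$val_metric)
  expect_equal(env$model$stage1$params, m2$stage1$params)
})

test_that("the returned model reproduces its recorded best validation metric", {
  env <- small_train_fixture()
  m <- env$model
  sp <- split_corpus(env$corpus, env$config$split_fractions,
                     seed = env$config$seed)
  cache <- new.env(parent = emptyenv())
  ft <- fact_type_names(env$schema)
  tp <- fp <- fn <- 0
  for (ar in sp$val) {
    E <- embed_tokens(ar$report, env$provider, cache)
    labs <- radfacts:::stage1_label_matrices(ar, ft)
    sc <- stage1_forward(m$stage1, E)
    pf <- sc$fact_scores >= env$config$threshold
    pa <- sc$anchor_scores >= env$config$threshold
    gf <- labs$Yf > 0; ga <- labs$Ya > 0
    tp <- tp + sum(pf & gf) + sum(pa & ga)
    fp <- fp + sum(pf & !gf) + sum(pa & !ga)
    fn <- fn + sum(!pf & gf) + sum(!pa & ga)
  }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  expect_equal(f1, attr(m$history, "best_metric")[["stage1"]])
})

test_that("checkpoint save/load verifies the bank-schema correspondence", {
  env <- small_train_fixture()
  p <- withr::local_tempfile(fileext = ".rds")
  save_extractor(env$model, p)
  m <- load_extractor(p)
  expect_setequal(names(m$stage2$banks), fact_type_names(env$schema))
  # a checkpoint whose banks do not match its schema is refused
  broken <- env$model
  broken$stage2$banks$finding_observed <- NULL
  saveRDS(broken, p)
  expect_error(load_extractor(p), "mismatch")
})

test_that("training rejects corpora that cannot produce a validation split", {
  sch <- default_schema()
  co <- generate_corpus(generator_config(seed = 82, n_reports = 3,
                                         facts_per_report_mean = 4))
  emb <- train_domain_embeddings(co, embedding_config(dim = 16, epochs = 1,
                                                      seed = 1))
  prov <- embedding_provider(emb)
  expect_error(
    train_extractor(co[1:2], sch, prov, train_config(max_epochs = 1)),
    "at least 3")
  # invalid facts are caught before any training happens
  co[[1]]$facts[[1]]$fact_span <- c(0, 10000)
  expect_error(
    train_extractor(co, sch, prov, train_config(max_epochs = 1)),
    "invalid fact")
})
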