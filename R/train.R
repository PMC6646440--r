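#' Training configuration for the two-stage extractor
#'
#' Training splits the corpus 80/10/10 at report level, trains the
#' document-level tagger first and then the per-fact-type refinement banks
#' on gold candidates (teacher forcing), each stage with early stopping on
#' its validation micro-F1 with a fixed patience. A single seed fans out to
#' the split, parameter initialisation, shuffling, and dropout.
#'
#' @param seed master seed.
#' @param split_fractions train/validation/test fractions.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs cap on epochs per stage.
#' @param learning_rate Adam learning rate (both stages).
#' @param hidden1,hidden2 GRU hidden size per direction for stage 1/2.
#' @param layers1 stacked GRU layers in stage 1.
#' @param dropout dropout on stage-1 GRU outputs.
#' @param context stage-2 context tokens each side of the fact span.
#' @param threshold decision threshold for span decoding.
#' @export
train_config <- function(seed = 1L, split_fractions = c(0.8, 0.1, 0.1),
                         patience = 3L, max_epochs = 30L,
                         learning_rate = 1e-3, hidden1 = 128L, hidden2 = 64L,
                         layers1 = 2L, dropout = 0.3, context = 20L,
                         threshold = 0.5) {
  stopifnot(patience >= 1, max_epochs >= 1)
  structure(list(seed = as.integer(seed), split_fractions = split_fractions,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(hidden2), layers1 = as.integer(layers1),
                 dropout = dropout, context = as.integer(context),
                 threshold = threshold),
            class = "rf_train_config")
}

# 0/1 token-label matrices for stage-1 supervision
stage1_label_matrices <- function(ar, fact_types) {
  nt <- nrow(ar$report$tokens)
  nf <- length(fact_types)
  Yf <- matrix(0, nt, nf)
  Ya <- matrix(0, nt, nf)
  for (f in ar$facts) {
    j <- match(f$fact_type, fact_types)
    if (is.na(j)) next
    Yf[interval_tokens(f$fact_span) + 1L, j] <- 1
    Ya[interval_tokens(f$anchor_span) + 1L, j] <- 1
  }
  list(Yf = Yf, Ya = Ya)
}

micro_f1_binary <- function(pred, gold) {
  tp <- sum(pred & gold)
  fp <- sum(pred & !gold)
  fn <- sum(!pred & gold)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# early-stopping driver shared by both stages.
# run_epoch(epoch) -> train loss; val_metric() -> scalar (higher = better);
# snapshot()/restore(s) capture model parameters.
fit_with_early_stopping <- function(stage_name, max_epochs, patience,
                                    run_epoch, val_metric, snapshot,
                                    verbose = FALSE) {
  history <- data.frame(stage = character(0), epoch = integer(0),
                        train_loss = numeric(0), val_metric = numeric(0),
                        timestamp = character(0), stringsAsFactors = FALSE)
  best <- -Inf
  best_epoch <- 0L
  best_state <- NULL
  since_best <- 0L
  for (epoch in seq_len(max_epochs)) {
    tl <- run_epoch(epoch)
    if (!is.finite(tl)) {
      stop("training aborted: non-finite loss in ", stage_name, " epoch ",
           epoch, call. = FALSE)
    }
    vm <- val_metric()
    history <- rbind(history, data.frame(
      stage = stage_name, epoch = epoch, train_loss = tl, val_metric = vm,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE))
    if (verbose) {
      message(sprintf("[%s] epoch %d loss %.4f val %.4f", stage_name, epoch,
                      tl, vm))
    }
    if (vm > best) {
      best <- vm
      best_epoch <- epoch
      best_state <- snapshot()
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  list(history = history, best_epoch = best_epoch, best_metric = best,
       best_state = best_state)
}

#' Train the two-stage fact extractor
#'
#' @param corpus list of `rf_annotated` reports (all facts must validate
#'   against `schema`).
#' @param schema an `rf_schema`.
#' @param provider an [embedding_provider()].
#' @param config an [train_config()].
#' @param verbose print per-epoch metrics.
#' @return an `rf_extractor`: stage-1 model, stage-2 banks, the schema, and
#'   a `history` data.frame (per stage/epoch training loss and validation
#'   micro-F1, with `best_epoch` attributes).
#' @export
train_extractor <- function(corpus, schema, provider,
                            config = train_config(), verbose = FALSE) {
  if (length(corpus) < 3L) {
    stop("training needs at least 3 reports for nonempty splits", call. = FALSE)
  }
  for (i in seq_along(corpus)) {
    nt <- nrow(corpus[[i]]$report$tokens)
    for (f in corpus[[i]]$facts) {
      v <- validate_fact(f, schema, nt)
      if (length(v)) {
        stop("corpus report ", i, " has invalid fact: ", v[1], call. = FALSE)
      }
    }
  }
  splits <- split_corpus(corpus, config$split_fractions, seed = config$seed)
  if (!length(splits$val)) stop("validation split is empty", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  embed1 <- function(ar) embed_tokens(ar$report, provider, cache)
  E_train <- lapply(splits$train, embed1)
  E_val <- lapply(splits$val, embed1)
  fact_types <- fact_type_names(schema)
  lab_train <- lapply(splits$train, stage1_label_matrices, fact_types = fact_types)
  lab_val <- lapply(splits$val, stage1_label_matrices, fact_types = fact_types)

  # ---- stage 1 ----
  s1 <- stage1_init(schema, provider$dim, hidden = config$hidden1,
                    layers = config$layers1, dropout = config$dropout,
                    threshold = config$threshold, seed = config$seed)
  opt1 <- adam_init(s1$params)
  n_train <- length(splits$train)
  epoch_seed <- function(stage, epoch) derive_seed(config$seed, 7717 * stage + epoch)
  run1 <- function(epoch) {
    total <- 0
    with_local_seed(epoch_seed(1L, epoch), {
      for (i in sample.int(n_train)) {
        lg <- stage1_loss_grads(s1, E_train[[i]], lab_train[[i]]$Yf,
                                lab_train[[i]]$Ya)
        st <- adam_step(s1$params, lg$grads, opt1, config$learning_rate)
        s1$params <<- st$params
        opt1 <<- st$state
        total <- total + lg$loss
      }
    })
    total / n_train
  }
  val1 <- function() {
    tp <- fp <- fn <- 0
    for (i in seq_along(E_val)) {
      sc <- stage1_forward(s1, E_val[[i]])
      pf <- sc$fact_scores >= config$threshold
      pa <- sc$anchor_scores >= config$threshold
      gf <- lab_val[[i]]$Yf > 0; ga <- lab_val[[i]]$Ya > 0
      tp <- tp + sum(pf & gf) + sum(pa & ga)
      fp <- fp + sum(pf & !gf) + sum(pa & !ga)
      fn <- fn + sum(!pf & gf) + sum(!pa & ga)
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  fit1 <- fit_with_early_stopping("stage1", config$max_epochs, config$patience,
                                  run1, val1, function() s1$params, verbose)
  s1$params <- fit1$best_state

  # ---- stage 2 (gold candidates, teacher forcing) ----
  s2 <- stage2_init(schema, provider$dim, hidden = config$hidden2,
                    context = config$context, threshold = config$threshold,
                    seed = config$seed + 1L)
  opt2 <- lapply(s2$banks, function(b) {
    adam_init(b[c("gru", "head_mod", "head_span")])
  })
  gold_candidates <- function(split_reports, E_list) {
    out <- list()
    for (i in seq_along(split_reports)) {
      for (f in split_reports[[i]]$facts) {
        cand <- list(fact_type = f$fact_type, fact_span = f$fact_span,
                     anchor_span = f$anchor_span)
        input <- build_candidate_input(cand, E_list[[i]], config$context)
        gold <- stage2_gold_labels(input, f, s2$banks[[f$fact_type]]$slots)
        out <- c(out, list(list(input = input, gold = gold)))
      }
    }
    out
  }
  cand_train <- gold_candidates(splits$train, E_train)
  cand_val <- gold_candidates(splits$val, E_val)
  run2 <- function(epoch) {
    total <- 0
    with_local_seed(epoch_seed(2L, epoch), {
      for (i in sample.int(length(cand_train))) {
        cc <- cand_train[[i]]
        ty <- cc$input$fact_type
        lg <- stage2_loss_grads(s2, cc$input, cc$gold)
        st <- adam_step(s2$banks[[ty]][c("gru", "head_mod", "head_span")],
                        lg$grads, opt2[[ty]], config$learning_rate)
        s2$banks[[ty]][c("gru", "head_mod", "head_span")] <<- st$params
        opt2[[ty]] <<- st$state
        total <- total + lg$loss
      }
    })
    total / length(cand_train)
  }
  val2 <- function() {
    tp <- fp <- fn <- 0
    for (cc in cand_val) {
      out <- stage2_forward(s2, cc$input)
      pred <- out$modifier_scores >= config$threshold
      gold <- cc$gold$Y > 0
      tp <- tp + sum(pred & gold)
      fp <- fp + sum(pred & !gold)
      fn <- fn + sum(!pred & gold)
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  snapshot2 <- function() lapply(s2$banks, function(b) {
    b[c("gru", "head_mod", "head_span")]
  })
  fit2 <- fit_with_early_stopping("stage2", config$max_epochs, config$patience,
                                  run2, val2, snapshot2, verbose)
  for (ty in names(s2$banks)) {
    s2$banks[[ty]][c("gru", "head_mod", "head_span")] <- fit2$best_state[[ty]]
  }

  history <- rbind(fit1$history, fit2$history)
  attr(history, "best_epoch") <- c(stage1 = fit1$best_epoch,
                                   stage2 = fit2$best_epoch)
  attr(history, "best_metric") <- c(stage1 = fit1$best_metric,
                                    stage2 = fit2$best_metric)
  structure(list(stage1 = s1, stage2 = s2, schema = schema,
                 config = config, history = history,
                 splits = list(train = vapply(splits$train, function(a) a$report$report_id, character(1)),
                               val = vapply(splits$val, function(a) a$report$report_id, character(1)),
                               test = vapply(splits$test, function(a) a$report$report_id, character(1)))),
            class = "rf_extractor")
}

#' @export
print.rf_extractor <- function(x, ...) {
  be <- attr(x$history, "best_epoch")
  bm <- attr(x$history, "best_metric")
  cat("<rf_extractor>", length(x$stage1$fact_types), "fact types\n")
  cat(sprintf("  stage1: best epoch %d (val micro-F1 %.3f)\n", be[["stage1"]],
              bm[["stage1"]]))
  cat(sprintf("  stage2: best epoch %d (val micro-F1 %.3f)\n", be[["stage2"]],
              bm[["stage2"]]))
  invisible(x)
}

#' Save / load a trained extractor
#'
#' Checkpoints store the stage-1 parameters and the per-fact-type stage-2
#' banks keyed by fact type name; loading verifies that the bank set equals
#' the schema's fact types.
#'
#' @param model an `rf_extractor`.
#' @param path file path (RDS).
#' @export
save_extractor <- function(model, path) {
  stopifnot(inherits(model, "rf_extractor"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rf_extractor")) stop("not an rf_extractor checkpoint",
                                             call. = FALSE)
  if (!setequal(names(model$stage2$banks), fact_type_names(model$schema))) {
    stop("checkpoint/schema mismatch: stage-2 banks ",
         paste(names(model$stage2$banks), collapse = ","),
         " do not match schema fact types", call. = FALSE)
  }
  model
}
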