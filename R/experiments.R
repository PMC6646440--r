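#' Scaled synthetic label-recovery experiment
#'
#' Reproduces, at desk scale and on synthetic data, the full pipeline study:
#' generate a gold-annotated training corpus with the default generator
#' conditions (skewed fact types, rare lab-result facts capped at 9,
#' conjunctions, typos, optional headers), train subword embeddings and the
#' two-stage extractor, and evaluate token-level micro-averaged metrics on
#' a separately generated held-out set. The default problem sizes (200
#' training reports, 25 held-out reports, 100-dimensional embeddings,
#' hidden sizes 64/32) are the package's scaled-down study conditions; they
#' are not a reproduction of any clinical corpus result.
#'
#' @param seed master seed driving generation, embedding training, and model
#'   training.
#' @param n_train,n_eval number of training / held-out reports.
#' @param embedding_dim dimensionality of the domain subword embeddings
#'   used by this experiment.
#' @param hidden1,hidden2 GRU hidden sizes for the two stages.
#' @param max_epochs per-stage epoch cap (early stopping, patience 3).
#' @param learning_rate Adam learning rate.
#' @param verbose print per-epoch training metrics.
#' @return a list with `eval` (an `rf_eval` on the held-out reports),
#'   `model`, `provider`, `train_type_counts` (facts per type seen in the
#'   full training corpus), and `eval_corpus`.
#' @export
label_recovery_experiment <- function(seed = 1L, n_train = 200L,
                                      n_eval = 25L, embedding_dim = 100L,
                                      hidden1 = 64L, hidden2 = 32L,
                                      max_epochs = 30L, learning_rate = 4e-3,
                                      verbose = FALSE) {
  schema <- default_schema()
  train_corpus <- generate_corpus(generator_config(
    seed = derive_seed(seed, 1), n_reports = n_train))
  # held-out set: same conditions, fresh stream; the rare-class cap applies
  # per generated corpus, so a few rare facts appear here for evaluation
  eval_corpus <- generate_corpus(generator_config(
    seed = derive_seed(seed, 2), n_reports = n_eval))
  emb <- train_domain_embeddings(train_corpus, embedding_config(
    dim = embedding_dim, epochs = 5, seed = derive_seed(seed, 3)))
  provider <- embedding_provider(emb)
  model <- train_extractor(train_corpus, schema, provider, train_config(
    seed = derive_seed(seed, 4), max_epochs = max_epochs,
    hidden1 = hidden1, hidden2 = hidden2, learning_rate = learning_rate),
    verbose = verbose)
  ev <- evaluate_extractor(model, eval_corpus, provider)
  types <- unlist(lapply(train_corpus, function(ar) {
    vapply(ar$facts, `[[`, character(1), "fact_type")
  }))
  list(eval = ev, model = model, provider = provider,
       train_type_counts = table(types), eval_corpus = eval_corpus)
}

#' Subword typo-robustness experiment
#'
#' Trains domain embeddings on a synthetic corpus, then for `n_words`
#' sampled vocabulary words (alphabetic, length >= 4) makes a single
#' interior-character typo and checks whether the typo'd form is closer (by
#' cosine) to its correct form than the median of 100 random vocabulary
#' words.
#'
#' @param seed master seed.
#' @param n_reports corpus size used to train the embeddings.
#' @param n_words number of sampled words.
#' @param dim embedding dimensionality.
#' @return list with `success_rate` (fraction of sampled words for which
#'   the typo stays closest) and `n_words`.
#' @export
subword_robustness_experiment <- function(seed = 1L, n_reports = 200L,
                                          n_words = 100L, dim = 100L) {
  corpus <- generate_corpus(generator_config(seed = derive_seed(seed, 11),
                                             n_reports = n_reports))
  emb <- train_domain_embeddings(corpus, embedding_config(
    dim = dim, epochs = 8, seed = derive_seed(seed, 12)))
  with_local_seed(derive_seed(seed, 13), {
    pool <- emb$vocab[nchar(emb$vocab) >= 4 & grepl("^[a-z]+$", emb$vocab)]
    words <- sample(pool, n_words, replace = length(pool) < n_words)
    ok <- 0L
    for (w in words) {
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      pos <- sample(seq(2, length(ch) - 1), 1)
      ch[pos] <- sample(setdiff(letters, ch[pos]), 1)
      typo <- paste(ch, collapse = "")
      rnd <- sample(emb$vocab, 100)
      V <- embedding_vectors(emb, c(w, typo, rnd))
      cs <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
      typo_cos <- cs(V[1, ], V[2, ])
      rand_cos <- apply(V[-(1:2), , drop = FALSE], 1, cs, b = V[1, ])
      if (typo_cos > stats::median(rand_cos)) ok <- ok + 1L
    }
    list(success_rate = ok / length(words), n_words = length(words))
  })
}
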