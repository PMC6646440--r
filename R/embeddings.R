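#' Subword embedding configuration
#'
#' Domain embeddings are trained with the skip-gram objective over the
#' report corpus, composing each word vector from the word's own vector
#' plus hashed character n-gram vectors. The subword composition gives
#' finite, spelling-informed vectors to out-of-vocabulary tokens and typos.
#' Tokens are lowercased for embedding purposes.
#'
#' @param dim embedding dimensionality (default 300).
#' @param min_char_ngram,max_char_ngram character n-gram range used for
#'   subword composition (boundary markers included).
#' @param bucket number of hash buckets for n-gram vectors.
#' @param window skip-gram context window (dynamic, as in word2vec).
#' @param epochs training epochs over the corpus.
#' @param learning_rate initial learning rate (linear decay).
#' @param negative negative samples per positive pair.
#' @param seed RNG seed; training is single-worker and fully reproducible.
#' @export
embedding_config <- function(dim = 300L, min_char_ngram = 3L,
                             max_char_ngram = 6L, bucket = 20000L,
                             window = 5L, epochs = 5L, learning_rate = 0.05,
                             negative = 5L, seed = 1L) {
  stopifnot(dim > 0, min_char_ngram >= 1, max_char_ngram >= min_char_ngram,
            bucket > 0, epochs >= 1)
  structure(list(dim = as.integer(dim), min_n = as.integer(min_char_ngram),
                 max_n = as.integer(max_char_ngram),
                 bucket = as.integer(bucket), window = as.integer(window),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "rf_embedding_config")
}

# normalize corpus input into a list of lowercase token vectors
corpus_token_lists <- function(corpus) {
  lapply(corpus, function(x) {
    if (inherits(x, "rf_annotated")) x <- x$report
    toks <- if (inherits(x, "rf_report")) {
      x$tokens$text
    } else if (is.character(x) && length(x) == 1L) {
      tokenize(x)$text
    } else if (is.character(x)) {
      x
    } else {
      stop("unsupported corpus element of class ", paste(class(x), collapse = "/"),
           call. = FALSE)
    }
    tolower(toks)
  })
}

#' Train domain subword embeddings
#'
#' @param corpus a list of annotated reports, `rf_report`s, raw text
#'   strings, or pre-tokenized character vectors.
#' @param config an [embedding_config()].
#' @return an `rf_embeddings` model supporting [embedding_vectors()] lookup
#'   for arbitrary strings.
#' @export
train_domain_embeddings <- function(corpus, config = embedding_config()) {
  sents <- corpus_token_lists(corpus)
  sents <- Filter(length, sents)
  if (!length(sents)) stop("empty corpus: no tokens to train on", call. = FALSE)
  vocab_counts <- table(unlist(sents, use.names = FALSE))
  vocab <- names(vocab_counts)
  ids <- lapply(sents, function(s) match(s, vocab) - 1L)
  fit <- cpp_subword_train(ids, vocab, as.numeric(vocab_counts),
                           config$dim, config$window, config$epochs,
                           config$learning_rate, config$negative,
                           config$min_n, config$max_n, config$bucket,
                           config$seed)
  structure(list(dim = config$dim, min_n = config$min_n, max_n = config$max_n,
                 bucket = config$bucket, vocab = vocab,
                 counts = as.numeric(vocab_counts),
                 word_vectors = fit$word_vectors,
                 ngram_vectors = fit$ngram_vectors,
                 config = config),
            class = "rf_embeddings")
}

#' @export
print.rf_embeddings <- function(x, ...) {
  cat("<rf_embeddings>", x$dim, "dims,", length(x$vocab), "vocabulary words,",
      x$min_n, "-", x$max_n, "char n-grams\n")
  invisible(x)
}

#' Look up embedding vectors for arbitrary strings
#'
#' Every query returns a finite vector of fixed length: in-vocabulary words
#' average their word vector with their n-gram vectors; unseen strings are
#' composed purely from n-gram vectors, so misspellings land near their
#' correct forms.
#'
#' @param model an `rf_embeddings` model.
#' @param words character vector of query strings.
#' @return numeric matrix `length(words) x dim`.
#' @export
embedding_vectors <- function(model, words) {
  stopifnot(inherits(model, "rf_embeddings"))
  out <- matrix(0, nrow = length(words), ncol = model$dim)
  lw <- tolower(words)
  wid <- match(lw, model$vocab)
  for (i in seq_along(words)) {
    ids <- cpp_subword_hashes(lw[i], model$min_n, model$max_n, model$bucket)
    cnt <- length(ids)
    v <- numeric(model$dim)
    if (cnt > 0) {
      v <- if (cnt == 1L) model$ngram_vectors[ids + 1L, ] else
        colSums(model$ngram_vectors[ids + 1L, , drop = FALSE])
    }
    if (!is.na(wid[i])) {
      v <- v + model$word_vectors[wid[i], ]
      cnt <- cnt + 1L
    }
    if (cnt > 0) out[i, ] <- v / cnt
  }
  out
}

#' Token embedding provider
#'
#' Combines the domain subword model with an optional general-purpose
#' pretrained static table. Per-token vectors are the concatenation
#' `[domain | general]` (order fixed); the general sub-vector is all zeros
#' when the general table is disabled or the token is absent from it.
#'
#' @param domain an `rf_embeddings` model.
#' @param general optional numeric matrix of pretrained vectors with words
#'   as rownames (e.g. loaded via [read_general_embeddings()]), or `NULL`
#'   (default: disabled).
#' @return an `rf_provider` with elements `domain`, `general`, `dim`
#'   (total per-token dimensionality read by downstream models).
#' @export
embedding_provider <- function(domain, general = NULL) {
  stopifnot(inherits(domain, "rf_embeddings"))
  gdim <- if (is.null(general)) 0L else ncol(general)
  structure(list(domain = domain, general = general,
                 dim = domain$dim + gdim), class = "rf_provider")
}

#' @rdname embedding_provider
#' @param path text file with one `word v1 v2 ...` entry per line (the
#'   common distribution format for pretrained static embeddings).
#' @export
read_general_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, " ", fixed = TRUE)
  parts <- Filter(function(p) length(p) > 1, parts)
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(mat) <- words
  mat
}

#' Embed the tokens of a report
#'
#' @param report an `rf_report` (or `rf_annotated`).
#' @param provider an [embedding_provider()].
#' @param cache optional environment used to memoise per-token vectors
#'   across reports.
#' @return numeric matrix `n_tokens x provider$dim`, one row per token.
#' @export
embed_tokens <- function(report, provider, cache = NULL) {
  if (inherits(report, "rf_annotated")) report <- report$report
  stopifnot(inherits(provider, "rf_provider"))
  toks <- report$tokens$text
  if (!length(toks)) return(matrix(0, 0, provider$dim))
  uniq <- unique(toks)
  need <- uniq
  if (!is.null(cache)) need <- uniq[!vapply(uniq, exists, logical(1), envir = cache)]
  if (length(need)) {
    dom <- embedding_vectors(provider$domain, need)
    gen <- matrix(0, nrow = length(need), ncol = provider$dim - provider$domain$dim)
    if (!is.null(provider$general)) {
      hit <- match(tolower(need), tolower(rownames(provider$general)))
      ok <- !is.na(hit)
      if (any(ok)) gen[ok, ] <- provider$general[hit[ok], , drop = FALSE]
    }
    full <- cbind(dom, gen)
    if (is.null(cache)) {
      rownames(full) <- need
      return(full[match(toks, need), , drop = FALSE])
    }
    for (i in seq_along(need)) assign(need[i], full[i, ], envir = cache)
  }
  out <- matrix(0, nrow = length(toks), ncol = provider$dim)
  for (i in seq_along(toks)) out[i, ] <- get(toks[i], envir = cache)
  out
}
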