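#' Stage-1 document tagger: fact-span and anchor-span token labeling
#'
#' The first network reads the embedded document through a 2-layer
#' bidirectional GRU; the concatenated forward/backward outputs feed two
#' independent dense heads, one scoring each token against every fact type
#' and one against every anchor type. Both heads use per-label sigmoids
#' (multi-class, multi-label: a token may belong to several overlapping
#' facts), trained with binary cross-entropy summed over the two heads with
#' equal weight. Dropout (default 0.3) is applied to the GRU outputs during
#' training only.
#'
#' @param schema an `rf_schema`; the heads size themselves from its fact
#'   and anchor type inventories.
#' @param input_dim per-token embedding dimensionality (from the provider).
#' @param hidden GRU hidden size per direction.
#' @param layers number of stacked GRU layers.
#' @param dropout dropout rate on GRU outputs during training.
#' @param threshold per-label decision threshold for span decoding.
#' @param seed initialisation seed.
#' @return an `rf_stage1` model.
#' @export
stage1_init <- function(schema, input_dim, hidden = 128L, layers = 2L,
                        dropout = 0.3, threshold = 0.5, seed = 1L) {
  stopifnot(inherits(schema, "rf_schema"), hidden > 0,
            dropout >= 0, dropout < 1)
  nf <- length(schema$fact_types)
  params <- with_local_seed(seed, list(
    gru = init_bigru(input_dim, hidden, layers),
    head_fact = init_linear(2 * hidden, nf),
    head_anchor = init_linear(2 * hidden, nf)))
  structure(list(params = params,
                 fact_types = fact_type_names(schema),
                 anchor_types = unname(anchor_names(schema)),
                 hyper = list(input_dim = input_dim, hidden = hidden,
                              layers = layers, dropout = dropout,
                              threshold = threshold)),
            class = "rf_stage1")
}

#' @rdname stage1_init
#' @param model an `rf_stage1` model.
#' @param E numeric matrix of token embeddings (`n_tokens x input_dim`).
#' @param training logical; when `TRUE` dropout is active (evaluation-mode
#'   forward is deterministic).
#' @return `stage1_forward()` returns a list with `fact_scores` and
#'   `anchor_scores` (each `n_tokens x n_types`, entries in `[0, 1]`, rows
#'   need not sum to 1) plus internals used by training.
#' @export
stage1_forward <- function(model, E, training = FALSE) {
  if (!nrow(E)) stop("empty document: stage 1 requires at least one token",
                     call. = FALSE)
  fw <- cpp_bigru_forward(E, model$params$gru)
  H <- fw$H
  mask <- NULL
  if (training && model$hyper$dropout > 0) {
    keep <- 1 - model$hyper$dropout
    mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                   nrow(H), ncol(H))
    H <- H * mask
  }
  lf <- add_bias_rows(H %*% model$params$head_fact$W, model$params$head_fact$b)
  la <- add_bias_rows(H %*% model$params$head_anchor$W,
                      model$params$head_anchor$b)
  list(fact_scores = sigmoid(lf), anchor_scores = sigmoid(la),
       fact_logits = lf, anchor_logits = la, H = H, cache = fw, mask = mask)
}

# loss + full gradient tree for one document (training mode)
stage1_loss_grads <- function(model, E, Yf, Ya) {
  out <- stage1_forward(model, E, training = TRUE)
  loss <- bce_from_logits(out$fact_logits, Yf) +
    bce_from_logits(out$anchor_logits, Ya)
  dlf <- (out$fact_scores - Yf) / length(Yf)
  dla <- (out$anchor_scores - Ya) / length(Ya)
  H <- out$H
  g_hf <- list(W = crossprod(H, dlf), b = colSums(dlf))
  g_ha <- list(W = crossprod(H, dla), b = colSums(dla))
  dH <- tcrossprod(dlf, model$params$head_fact$W) +
    tcrossprod(dla, model$params$head_anchor$W)
  if (!is.null(out$mask)) dH <- dH * out$mask
  bw <- cpp_bigru_backward(dH, model$params$gru, out$cache$caches,
                           out$cache$inputs)
  list(loss = loss,
       grads = list(gru = bw$grads, head_fact = g_hf, head_anchor = g_ha))
}

#' Decode thresholded token scores into spans
#'
#' Returns the maximal runs of consecutive tokens whose score meets the
#' threshold, as sorted, disjoint 0-based half-open token intervals.
#'
#' @param scores numeric vector of per-token scores for one label.
#' @param threshold decision threshold.
#' @return list of token intervals (possibly empty).
#' @examples
#' decode_spans(c(0.9, 0.9, 0.1, 0.8), 0.5)  # (0,2) and (3,4)
#' @export
decode_spans <- function(scores, threshold = 0.5) {
  if (!length(scores)) return(list())
  above <- scores >= threshold
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i] - 1L, ends[i]))
}

#' Form fact candidates from decoded fact and anchor spans
#'
#' For every predicted anchor span lying inside a predicted fact span of
#' the compatible fact type (the schema couples each anchor type to the
#' fact type that owns it), one candidate is created. When an anchor lies
#' inside several nested or overlapping compatible fact spans, only the
#' smallest enclosing fact span is used (ties broken toward the earliest
#' start), mirroring the minimal-span labeling convention. Candidates are
#' sorted by fact-span start, then anchor start.
#'
#' @param fact_spans named list: fact type -> list of token intervals.
#' @param anchor_spans named list: anchor type -> list of token intervals.
#' @param schema an `rf_schema`.
#' @return list of candidates, each `list(fact_type, fact_span, anchor_span)`.
#' @export
generate_candidates <- function(fact_spans, anchor_spans, schema) {
  anchors_of <- anchor_names(schema)
  out <- list()
  for (atype in names(anchor_spans)) {
    ftype <- fact_type_for_anchor(schema, atype)
    if (is.na(ftype)) next
    fspans <- fact_spans[[ftype]] %||% list()
    if (!length(fspans)) next
    for (a in anchor_spans[[atype]]) {
      enclosing <- Filter(function(fs) interval_within(a, fs), fspans)
      if (!length(enclosing)) next
      widths <- vapply(enclosing, function(fs) fs[2] - fs[1], numeric(1))
      starts <- vapply(enclosing, `[`, numeric(1), 1L)
      best <- order(widths, starts)[1]
      out <- c(out, list(list(fact_type = ftype,
                              fact_span = enclosing[[best]],
                              anchor_span = a)))
    }
  }
  if (length(out) > 1) {
    ord <- order(vapply(out, function(c) c$fact_span[1], numeric(1)),
                 vapply(out, function(c) c$anchor_span[1], numeric(1)))
    out <- out[ord]
  }
  out
}

# decode both score matrices and produce candidates for one document
stage1_candidates <- function(model, scores, schema) {
  th <- model$hyper$threshold
  fact_spans <- lapply(seq_along(model$fact_types), function(j) {
    decode_spans(scores$fact_scores[, j], th)
  })
  names(fact_spans) <- model$fact_types
  anchor_spans <- lapply(seq_along(model$anchor_types), function(j) {
    decode_spans(scores$anchor_scores[, j], th)
  })
  names(anchor_spans) <- model$anchor_types
  generate_candidates(fact_spans, anchor_spans, schema)
}
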