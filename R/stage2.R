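#' Stage-2 refinement network: modifier slot filling and span boundaries
#'
#' The second network processes one fact candidate at a time. Its input is
#' the embedding matrix of the candidate window - the predicted fact span
#' extended by up to `context` tokens on each side (clipped, not padded, at
#' document boundaries) - with one extra column: a 0/1 anchor mask marking
#' the predicted anchor tokens. A bidirectional GRU encodes the window;
#' one head emits per-token sigmoid scores for every modifier slot of the
#' fact type plus one anchor-refinement column, and a second head emits
#' begin/end scores whose argmax over window positions gives the refined
#' fact span. Each registered fact type owns a separate parameter bank;
#' the fact type predicted by stage 1 selects the bank.
#'
#' The training loss is the sum of binary cross-entropy over the token-level
#' slot labels and softmax cross-entropy for the begin and end positions.
#'
#' @param schema an `rf_schema`.
#' @param input_dim embedding dimensionality (the mask column is added
#'   internally, so banks see `input_dim + 1` features).
#' @param hidden GRU hidden size per direction.
#' @param context tokens of context included before and after the predicted
#'   fact span (default 20).
#' @param threshold decision threshold for modifier span decoding.
#' @param seed initialisation seed.
#' @return an `rf_stage2` model holding one parameter bank per fact type.
#' @export
stage2_init <- function(schema, input_dim, hidden = 64L, context = 20L,
                        threshold = 0.5, seed = 1L) {
  stopifnot(inherits(schema, "rf_schema"), context >= 0)
  banks <- with_local_seed(seed, {
    lapply(schema$fact_types, function(ft) {
      ns <- length(ft$modifiers)
      list(gru = init_bigru(input_dim + 1L, hidden, 1L),
           head_mod = init_linear(2 * hidden, ns + 1L),  # +1: anchor refinement
           head_span = init_linear(2 * hidden, 2L),       # begin, end
           slots = names(ft$modifiers))
    })
  })
  structure(list(banks = banks,
                 hyper = list(input_dim = input_dim, hidden = hidden,
                              context = context, threshold = threshold)),
            class = "rf_stage2")
}

#' Build the stage-2 input for one candidate
#'
#' @param candidate `list(fact_type, fact_span, anchor_span)` in document
#'   token coordinates.
#' @param E document embedding matrix (`n_tokens x input_dim`).
#' @param context context tokens on each side of the fact span.
#' @return list with `X` (window embeddings with the anchor-mask column
#'   appended), `window` (document-coordinate interval), `offsets`
#'   (document token index of each window row), `fact_type`.
#' @export
build_candidate_input <- function(candidate, E, context = 20L) {
  nt <- nrow(E)
  fs <- candidate$fact_span
  window <- as.integer(c(max(0L, fs[1] - context), min(nt, fs[2] + context)))
  offsets <- seq.int(window[1], window[2] - 1L)
  mask <- as.numeric(offsets >= candidate$anchor_span[1] &
                       offsets < candidate$anchor_span[2])
  X <- cbind(E[offsets + 1L, , drop = FALSE], mask)
  dimnames(X) <- NULL
  list(X = X, window = window, offsets = offsets,
       fact_type = candidate$fact_type)
}

#' @rdname stage2_init
#' @param model an `rf_stage2` model.
#' @param input a [build_candidate_input()] result.
#' @return `stage2_forward()` returns `modifier_scores` (window length x
#'   (slots + 1), last column = anchor refinement), `begin_scores`,
#'   `end_scores` (one per window position), and the slot names.
#' @export
stage2_forward <- function(model, input) {
  bank <- model$banks[[input$fact_type]]
  if (is.null(bank)) {
    stop("no stage-2 parameter bank for fact type '", input$fact_type, "'",
         call. = FALSE)
  }
  fw <- cpp_bigru_forward(input$X, bank$gru)
  H <- fw$H
  lm <- add_bias_rows(H %*% bank$head_mod$W, bank$head_mod$b)
  ls <- add_bias_rows(H %*% bank$head_span$W, bank$head_span$b)
  list(modifier_scores = sigmoid(lm), begin_scores = ls[, 1],
       end_scores = ls[, 2], modifier_logits = lm, span_logits = ls,
       slots = bank$slots, H = H, cache = fw)
}

#' Refine a fact span from begin/end position scores
#'
#' The refined span runs from the argmax of the begin scores to the argmax
#' of the end scores (inclusive token, so the interval end is argmax + 1),
#' both mapped back to document coordinates; ties break toward the
#' earliest position. If the decoded end does not lie after the decoded
#' begin, the fallback span (the stage-1 fact span) is returned.
#'
#' @param begin_scores,end_scores numeric vectors over window positions.
#' @param offsets document token index per window position.
#' @param fallback interval returned when the decode is inconsistent.
#' @return a document-coordinate token interval.
#' @export
refine_span <- function(begin_scores, end_scores, offsets, fallback) {
  stopifnot(length(begin_scores) == length(end_scores))
  b <- which.max(begin_scores)  # which.max takes the earliest maximum
  e <- which.max(end_scores)
  begin_doc <- offsets[b]
  end_doc <- offsets[e] + 1L
  if (end_doc <= begin_doc) return(as.integer(fallback))
  c(begin_doc, end_doc)
}

# gold labels for a candidate window given the gold fact
stage2_gold_labels <- function(input, fact, slots) {
  L <- length(input$offsets)
  Y <- matrix(0, L, length(slots) + 1L)
  for (m in fact$modifiers) {
    j <- match(m$slot, slots)
    if (is.na(j)) next
    for (iv in m$spans) {
      w <- which(input$offsets >= iv[1] & input$offsets < iv[2])
      Y[w, j] <- 1
    }
  }
  w <- which(input$offsets >= fact$anchor_span[1] &
               input$offsets < fact$anchor_span[2])
  Y[w, length(slots) + 1L] <- 1
  gb <- match(fact$fact_span[1], input$offsets)
  ge <- match(fact$fact_span[2] - 1L, input$offsets)
  if (is.na(gb) || is.na(ge)) {
    stop("gold fact boundary outside candidate window", call. = FALSE)
  }
  list(Y = Y, begin = gb, end = ge)
}

#' Stage-2 training loss
#'
#' Sum of token-level binary cross-entropy over modifier (and anchor
#' refinement) labels and softmax cross-entropy for the begin and end
#' positions. With a uniform begin distribution over a window of length L
#' the begin term equals `log(L)`.
#'
#' @param output a [stage2_forward()] result.
#' @param gold list with `Y` (window x slots+1 0/1 labels), `begin`, `end`
#'   (1-based window positions of the gold boundaries).
#' @return scalar loss (nonnegative).
#' @export
stage2_loss <- function(output, gold) {
  ce_pos <- function(logits, k) -logits[k] + log_sum_exp(logits)
  bce_from_logits(output$modifier_logits, gold$Y) +
    ce_pos(output$span_logits[, 1], gold$begin) +
    ce_pos(output$span_logits[, 2], gold$end)
}

# loss + gradients for one candidate
stage2_loss_grads <- function(model, input, gold) {
  bank <- model$banks[[input$fact_type]]
  out <- stage2_forward(model, input)
  loss <- stage2_loss(out, gold)
  dm <- (out$modifier_scores - gold$Y) / length(gold$Y)
  pb <- exp(out$span_logits[, 1] - log_sum_exp(out$span_logits[, 1]))
  pe <- exp(out$span_logits[, 2] - log_sum_exp(out$span_logits[, 2]))
  pb[gold$begin] <- pb[gold$begin] - 1
  pe[gold$end] <- pe[gold$end] - 1
  ds <- cbind(pb, pe)
  H <- out$H
  g_mod <- list(W = crossprod(H, dm), b = colSums(dm))
  g_span <- list(W = crossprod(H, ds), b = colSums(ds))
  dH <- tcrossprod(dm, bank$head_mod$W) + tcrossprod(ds, bank$head_span$W)
  bw <- cpp_bigru_backward(dH, bank$gru, out$cache$caches, out$cache$inputs)
  list(loss = loss,
       grads = list(gru = bw$grads, head_mod = g_mod, head_span = g_span))
}

# run stage 2 on a candidate and assemble a predicted fact
stage2_predict_fact <- function(model, candidate, E) {
  input <- build_candidate_input(candidate, E, model$hyper$context)
  out <- stage2_forward(model, input)
  refined <- refine_span(out$begin_scores, out$end_scores, input$offsets,
                         candidate$fact_span)
  th <- model$hyper$threshold
  # anchor refinement: contiguous run in the anchor column overlapping the
  # stage-1 anchor; fall back to the stage-1 anchor
  nslot <- length(out$slots)
  aruns <- decode_spans(out$modifier_scores[, nslot + 1L], th)
  anchor <- candidate$anchor_span
  for (run in aruns) {
    iv <- c(input$offsets[run[1] + 1L], input$offsets[run[2]] + 1L)
    if (iv[1] < candidate$anchor_span[2] && iv[2] > candidate$anchor_span[1]) {
      anchor <- iv
      break
    }
  }
  # the assembled fact must contain its anchor
  refined <- c(min(refined[1], anchor[1]), max(refined[2], anchor[2]))
  mods <- list()
  if (nslot > 0) for (j in seq_len(nslot)) {
    runs <- decode_spans(out$modifier_scores[, j], th)
    ivs <- list()
    for (run in runs) {
      iv <- c(input$offsets[run[1] + 1L], input$offsets[run[2]] + 1L)
      iv <- c(max(iv[1], refined[1]), min(iv[2], refined[2]))  # clip to fact
      if (iv[1] < iv[2]) ivs <- c(ivs, list(iv))
    }
    if (length(ivs)) {
      mods <- c(mods, list(list(slot = out$slots[j], spans = ivs)))
    }
  }
  rf_fact(candidate$fact_type, refined, anchor, modifiers = mods)
}
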