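#' Token-level label sets for evaluation
#'
#' Evaluation is at word-token granularity: annotations are expanded into
#' sets of (token index, label) pairs and compared as sets, so multiple
#' overlapping same-label facts collapse to one pair per token. Three
#' families are reported:
#' \describe{
#'   \item{fact}{pairs `(t, fact_type)` for every token inside any fact
#'     span of that type;}
#'   \item{anchor}{pairs `(t, anchor_type)` for anchor tokens;}
#'   \item{all}{all labeled pieces of information: anchor pairs plus
#'     `(t, fact_type:slot)` pairs for modifier tokens (slot labels are
#'     namespaced per fact type, since slot semantics are type-specific).}
#' }
#'
#' @param facts list of `rf_fact` annotations (gold or predicted).
#' @param schema an `rf_schema`.
#' @param family one of `"fact"`, `"anchor"`, `"all"`.
#' @return character vector of unique `"token|label"` pairs.
#' @export
token_label_sets <- function(facts, schema, family = c("fact", "anchor", "all")) {
  family <- match.arg(family)
  anchors <- anchor_names(schema)
  pairs <- character(0)
  for (f in facts) {
    if (family == "fact") {
      pairs <- c(pairs, paste0(interval_tokens(f$fact_span), "|", f$fact_type))
    } else if (family == "anchor") {
      pairs <- c(pairs, paste0(interval_tokens(f$anchor_span), "|",
                               anchors[[f$fact_type]]))
    } else {
      pairs <- c(pairs, paste0(interval_tokens(f$anchor_span), "|",
                               anchors[[f$fact_type]]))
      for (m in f$modifiers) {
        pairs <- c(pairs, paste0(intervals_tokens(m$spans), "|",
                                 f$fact_type, ":", m$slot))
      }
    }
  }
  unique(pairs)
}

#' Micro-averaged precision, recall, and F1 over label sets
#'
#' Pools true/false positives and false negatives over all (token, label)
#' pairs before computing the metrics. Undefined ratios (zero denominator)
#' are reported as 0.
#'
#' @param gold,predicted character vectors of unique pair keys (as from
#'   [token_label_sets()]).
#' @return list of class `rf_prf` with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @examples
#' micro_prf(c("0|a", "1|a"), c("1|a", "2|a"))  # P = R = F1 = 0.5
#' @export
micro_prf <- function(gold, predicted) {
  gold <- unique(gold)
  predicted <- unique(predicted)
  tp <- length(intersect(gold, predicted))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  prf_from_counts(tp, fp, fn)
}

prf_from_counts <- function(tp, fp, fn) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f1), class = "rf_prf")
}

#' @export
print.rf_prf <- function(x, ...) {
  cat(sprintf("P %.3f R %.3f F1 %.3f (tp %d fp %d fn %d)\n", x$precision,
              x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Extract facts from a report with a trained extractor
#'
#' Runs the full pipeline: stage-1 token scoring, span decoding, candidate
#' generation, then stage-2 refinement and slot filling per candidate.
#' Predicted facts use the refined stage-2 spans. Identical
#' (type, anchor, span) duplicates are collapsed. Deterministic
#' (evaluation-mode forward).
#'
#' @param model an `rf_extractor`.
#' @param report an `rf_report` (or `rf_annotated`).
#' @param provider the [embedding_provider()] used in training.
#' @param cache optional memoisation environment for token vectors.
#' @return list of predicted `rf_fact`s (possibly empty).
#' @export
extract_facts <- function(model, report, provider, cache = NULL) {
  if (inherits(report, "rf_annotated")) report <- report$report
  if (!nrow(report$tokens)) return(list())
  E <- embed_tokens(report, provider, cache)
  scores <- stage1_forward(model$stage1, E)
  cands <- stage1_candidates(model$stage1, scores, model$schema)
  if (!length(cands)) return(list())
  facts <- lapply(cands, function(cc) stage2_predict_fact(model$stage2, cc, E))
  keys <- vapply(facts, function(f) {
    paste(f$fact_type, f$fact_span[1], f$fact_span[2], f$anchor_span[1],
          f$anchor_span[2], sep = "_")
  }, character(1))
  facts[!duplicated(keys)]
}

#' Evaluate an extractor on annotated reports
#'
#' Computes token-level micro-averaged precision/recall/F1 for the three
#' reporting families (fact spans, anchors, all labeled information) plus
#' per-class breakdowns, pooling counts over all reports.
#'
#' @param model an `rf_extractor`.
#' @param reports list of `rf_annotated` test reports.
#' @param provider the training [embedding_provider()].
#' @param predictions optional precomputed list of predicted fact lists
#'   (parallel to `reports`), e.g. to evaluate oracle or external output.
#' @return an `rf_eval` with elements `fact_span`, `anchor`, `all_spans`
#'   (each `rf_prf`) and `per_class` (named list of `rf_prf` keyed by
#'   `family/label`).
#' @export
evaluate_extractor <- function(model, reports, provider, predictions = NULL) {
  schema <- model$schema
  if (is.null(predictions)) {
    cache <- new.env(parent = emptyenv())
    predictions <- lapply(reports, function(ar) {
      extract_facts(model, ar, provider, cache)
    })
  }
  fams <- c("fact", "anchor", "all")
  counts <- list()   # label -> c(tp, fp, fn) per family
  tot <- list(fact = c(0, 0, 0), anchor = c(0, 0, 0), all = c(0, 0, 0))
  for (i in seq_along(reports)) {
    for (fam in fams) {
      g <- token_label_sets(reports[[i]]$facts, schema, fam)
      p <- token_label_sets(predictions[[i]], schema, fam)
      tp_set <- intersect(g, p)
      fp_set <- setdiff(p, g)
      fn_set <- setdiff(g, p)
      tot[[fam]] <- tot[[fam]] + c(length(tp_set), length(fp_set), length(fn_set))
      lab <- function(keys) sub("^[0-9]+\\|", "", keys)
      for (set_name in c("tp", "fp", "fn")) {
        keys <- switch(set_name, tp = tp_set, fp = fp_set, fn = fn_set)
        if (!length(keys)) next
        tl <- table(lab(keys))
        for (l in names(tl)) {
          key <- paste0(fam, "/", l)
          cur <- counts[[key]] %||% c(tp = 0, fp = 0, fn = 0)
          cur[[set_name]] <- cur[[set_name]] + tl[[l]]
          counts[[key]] <- cur
        }
      }
    }
  }
  per_class <- lapply(counts, function(x) prf_from_counts(x[["tp"]], x[["fp"]],
                                                          x[["fn"]]))
  structure(list(
    fact_span = prf_from_counts(tot$fact[1], tot$fact[2], tot$fact[3]),
    anchor = prf_from_counts(tot$anchor[1], tot$anchor[2], tot$anchor[3]),
    all_spans = prf_from_counts(tot$all[1], tot$all[2], tot$all[3]),
    per_class = per_class), class = "rf_eval")
}

#' @export
print.rf_eval <- function(x, ...) {
  cat("<rf_eval> token-level micro-averaged metrics\n")
  for (fam in c("fact_span", "anchor", "all_spans")) {
    m <- x[[fam]]
    cat(sprintf("  %-10s P %5.1f%%  R %5.1f%%  F1 %5.1f%%\n", fam,
                100 * m$precision, 100 * m$recall, 100 * m$f1))
  }
  invisible(x)
}
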