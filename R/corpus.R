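#' Split a corpus into train / validation / test partitions
#'
#' Splitting is at whole-report granularity (never sentence-level, to avoid
#' leaking report-specific style across partitions), reproducible for a
#' fixed seed, with partition sizes fixed by largest-remainder rounding of
#' the requested fractions.
#'
#' @param reports list of reports (any type; treated opaquely).
#' @param fractions numeric vector of positive fractions summing to 1.
#' @param seed integer seed controlling the permutation.
#' @return list of `length(fractions)` disjoint report lists, named
#'   `train`/`val`/`test` when three fractions are given.
#' @examples
#' sp <- split_corpus(as.list(1:10), c(0.8, 0.1, 0.1), seed = 1)
#' lengths(sp)
#' @export
split_corpus <- function(reports, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  n <- length(reports)
  k <- length(fractions)
  if (n < k) stop("need at least ", k, " reports for ", k, " nonempty partitions",
                  call. = FALSE)
  # largest-remainder apportionment
  quota <- n * fractions
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_by_frac <- order(quota - sizes, decreasing = TRUE)
    sizes[order_by_frac[seq_len(rem)]] <- sizes[order_by_frac[seq_len(rem)]] + 1
  }
  if (any(sizes == 0)) {
    stop("fewer reports than nonempty partitions at the requested fractions",
         call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n))
  bounds <- cumsum(c(0, sizes))
  out <- lapply(seq_len(k), function(i) {
    reports[perm[(bounds[i] + 1L):bounds[i + 1L]]]
  })
  if (k == 3L) names(out) <- c("train", "val", "test")
  out
}

#' Corpus-level annotation statistics
#'
#' Counts facts and labeled spans and measures token coverage across an
#' annotated corpus. A "labeled piece of information" is one anchor span
#' plus one per modifier slot instance (a discontiguous slot instance still
#' counts once). Token coverage is the fraction of word tokens lying inside
#' at least one fact span. Means are computed exactly; rounding is left to
#' presentation.
#'
#' @param reports list of `rf_annotated` objects.
#' @return list of class `rf_corpus_stats` with `n_reports`, `n_facts`,
#'   `n_spans`, `facts_per_report`, `spans_per_fact` (`NA` when the corpus
#'   has no facts), `token_coverage`, `n_tokens`.
#' @export
corpus_stats <- function(reports) {
  stopifnot(length(reports) >= 1L)
  n_reports <- length(reports)
  n_facts <- 0L
  n_spans <- 0L
  tok_total <- 0L
  tok_covered <- 0L
  for (ar in reports) {
    nt <- nrow(ar$report$tokens)
    tok_total <- tok_total + nt
    covered <- logical(nt)
    for (f in ar$facts) {
      n_facts <- n_facts + 1L
      n_spans <- n_spans + 1L + length(f$modifiers)
      covered[interval_tokens(f$fact_span) + 1L] <- TRUE
    }
    tok_covered <- tok_covered + sum(covered)
  }
  structure(list(
    n_reports = n_reports,
    n_facts = n_facts,
    n_spans = n_spans,
    n_tokens = tok_total,
    facts_per_report = n_facts / n_reports,
    spans_per_fact = if (n_facts > 0) n_spans / n_facts else NA_real_,
    token_coverage = if (tok_total > 0) tok_covered / tok_total else NA_real_
  ), class = "rf_corpus_stats")
}

#' @export
print.rf_corpus_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<rf_corpus_stats> %d reports, %d facts, %d labeled spans\n",
    "  facts/report  %.1f\n  spans/fact    %s\n  token coverage %.1f%% of %d tokens\n"),
    x$n_reports, x$n_facts, x$n_spans, x$facts_per_report,
    if (is.na(x$spans_per_fact)) "-" else sprintf("%.2f", x$spans_per_fact),
    100 * x$token_coverage, x$n_tokens))
  invisible(x)
}
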