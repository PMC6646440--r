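# Shared fixtures and independent brute-force oracles used across tests.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(v) v[sample.int(length(v), 1)]

tiny_schema <- function() {
  rf_schema(list(
    list(name = "finding_observed", anchor = "finding",
         modifiers = list("negation", "location", "size")),
    list(name = "had_procedure", anchor = "procedure",
         modifiers = list("temporal_qualifier"))
  ))
}

# random schema with unique names, for round-trip property tests
random_schema <- function() {
  k <- sample(1:4, 1)
  used_slots <- c("negation", "uncertainty", "location", "size",
                  "description", "change_over_time", "desired_timing",
                  "temporal_qualifier", "person_qualifier")
  fts <- lapply(seq_len(k), function(i) {
    nmods <- sample(0:4, 1)
    mods <- if (nmods > 0) {
      as.list(sample(used_slots, nmods))
    } else {
      list()
    }
    list(name = paste0("type_", i, "_", paste(sample(letters, 4), collapse = "")),
         anchor = paste0("anchor_", i), modifiers = mods)
  })
  rf_schema(fts, version = sprintf("%d.%d", sample(0:3, 1), sample(0:9, 1)))
}

# random sorted disjoint intervals inside [lo, hi)
random_intervals <- function(lo, hi, max_n = 2) {
  pool <- seq.int(lo, hi - 1)
  k <- min(length(pool), sample(1:max_n, 1) * 2)
  covered <- sort(pool[sample.int(length(pool), k)])
  # convert covered token set to maximal runs
  runs <- list()
  start <- covered[1]
  prev <- covered[1]
  for (t in covered[-1]) {
    if (t != prev + 1) {
      runs <- c(runs, list(c(start, prev + 1)))
      start <- t
    }
    prev <- t
  }
  runs <- c(runs, list(c(start, prev + 1)))
  runs
}

# random valid annotated report against a given schema
random_annotated <- function(schema, id = "r1") {
  nt <- sample(8:30, 1)
  words <- replicate(nt, paste(sample(letters, sample(2:6, 1), replace = TRUE),
                               collapse = ""))
  report <- tokenize_report(paste(words, collapse = " "), report_id = id)
  nf <- sample(0:4, 1)
  facts <- list()
  for (i in seq_len(nf)) {
    ft <- schema$fact_types[[sample.int(length(schema$fact_types), 1)]]
    s <- pick1(0:(nt - 2))
    e <- pick1((s + 2):nt)
    as <- pick1(s:(e - 1))
    ae <- pick1((as + 1):e)
    mods <- list()
    if (length(ft$modifiers) && e - s >= 2 && stats::runif(1) < 0.8) {
      slot <- sample(names(ft$modifiers), 1)
      mods[[slot]] <- random_intervals(s, e)
    }
    facts <- c(facts, list(rf_fact(ft$name, c(s, e), c(as, ae),
                                   modifiers = mods)))
  }
  annotated_report(report, facts)
}

# ---- independent oracles ---------------------------------------------------

# maximal threshold runs by explicit pairwise scan
oracle_decode_spans <- function(scores, threshold) {
  n <- length(scores)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(scores[i:j] >= threshold) &&
          (i == 1 || scores[i - 1] < threshold) &&
          (j == n || scores[j + 1] < threshold)) {
        out <- c(out, list(c(i - 1L, j)))
      }
    }
  }
  out
}

# enumerate all (anchor, fact-span) containment pairs, filter by schema
# compatibility, apply the smallest-enclosing rule, sort
oracle_candidates <- function(fact_spans, anchor_spans, schema) {
  anchors <- anchor_names(schema)
  out <- list()
  for (atype in names(anchor_spans)) {
    ftype <- names(anchors)[match(atype, anchors)]
    if (is.na(ftype)) next
    for (a in anchor_spans[[atype]]) {
      best <- NULL
      for (fs in fact_spans[[ftype]]) {
        if (a[1] >= fs[1] && a[2] <= fs[2]) {
          if (is.null(best) ||
              (fs[2] - fs[1]) < (best[2] - best[1]) ||
              ((fs[2] - fs[1]) == (best[2] - best[1]) && fs[1] < best[1])) {
            best <- fs
          }
        }
      }
      if (!is.null(best)) {
        out <- c(out, list(list(fact_type = ftype, fact_span = best,
                                anchor_span = a)))
      }
    }
  }
  if (length(out) > 1) {
    ord <- order(vapply(out, function(c) c$fact_span[1], numeric(1)),
                 vapply(out, function(c) c$anchor_span[1], numeric(1)))
    out <- out[ord]
  }
  out
}

oracle_refine_span <- function(begin_scores, end_scores, offsets, fallback) {
  b <- 1
  for (i in seq_along(begin_scores)) if (begin_scores[i] > begin_scores[b]) b <- i
  e <- 1
  for (i in seq_along(end_scores)) if (end_scores[i] > end_scores[e]) e <- i
  lo <- offsets[b]
  hi <- offsets[e] + 1L
  if (hi <= lo) return(as.integer(fallback))
  c(lo, hi)
}

oracle_micro_prf <- function(gold, predicted) {
  gold <- unique(gold)
  predicted <- unique(predicted)
  tp <- fp <- fn <- 0
  for (g in gold) {
    hit <- FALSE
    for (p in predicted) if (identical(g, p)) hit <- TRUE
    if (hit) tp <- tp + 1 else fn <- fn + 1
  }
  for (p in predicted) {
    hit <- FALSE
    for (g in gold) if (identical(g, p)) hit <- TRUE
    if (!hit) fp <- fp + 1
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
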