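#' Fact annotations and annotated reports
#'
#' `rf_fact()` builds a single fact instance: a fact type, the minimal
#' contiguous fact span, the contiguous anchor span, and zero or more
#' modifier slot instances. All spans are 0-based half-open token intervals
#' `c(start, end)`. A modifier slot instance may be discontiguous (an
#' ordered list of disjoint intervals); the anchor may not.
#'
#' @param fact_type fact type name (must exist in the active schema to
#'   validate).
#' @param fact_span token interval of the complete fact.
#' @param anchor_span token interval of the anchor entity.
#' @param modifiers named list mapping slot name to an interval or list of
#'   intervals, or a list of `list(slot=, spans=)` records.
#' @return an object of class `rf_fact`.
#' @examples
#' rf_fact("finding_observed", c(0, 4), c(1, 2),
#'         modifiers = list(negation = c(0, 1)))
#' @export
rf_fact <- function(fact_type, fact_span, anchor_span, modifiers = list()) {
  mods <- list()
  if (length(modifiers)) {
    if (!is.null(names(modifiers)) && any(nzchar(names(modifiers)))) {
      mods <- lapply(seq_along(modifiers), function(i) {
        list(slot = names(modifiers)[i],
             spans = as_interval_list(modifiers[[i]]))
      })
    } else {
      mods <- lapply(modifiers, function(m) {
        list(slot = m$slot, spans = as_interval_list(m$spans))
      })
    }
  }
  anchor <- as_interval_list(anchor_span)
  if (length(anchor) == 1L) anchor <- anchor[[1]]
  structure(list(fact_type = as.character(fact_type),
                 fact_span = as.integer(fact_span),
                 anchor_span = anchor,
                 modifiers = mods),
            class = "rf_fact")
}

#' @export
print.rf_fact <- function(x, ...) {
  mods <- vapply(x$modifiers, function(m) {
    paste0(m$slot, "[", paste(vapply(m$spans, function(iv)
      paste0(iv[1], ":", iv[2]), character(1)), collapse = ","), "]")
  }, character(1))
  cat(sprintf("<rf_fact> %s span=%d:%d anchor=%s %s\n", x$fact_type,
              x$fact_span[1], x$fact_span[2],
              paste0(x$anchor_span[1], ":", x$anchor_span[2]),
              paste(mods, collapse = " ")))
  invisible(x)
}

#' @rdname rf_fact
#' @param report an `rf_report`.
#' @param facts list of `rf_fact` annotations on `report`.
#' @export
annotated_report <- function(report, facts = list()) {
  stopifnot(inherits(report, "rf_report"))
  structure(list(report = report, facts = facts), class = "rf_annotated")
}

#' @export
print.rf_annotated <- function(x, ...) {
  cat("<rf_annotated>", x$report$report_id, "-", nrow(x$report$tokens),
      "tokens,", length(x$facts), "facts\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Standoff annotation file format (line-delimited JSON).
#
# Line 1 is a header: {"format":"radfacts-standoff","format_version":1,
# "schema_version":..., "tokenizer":...}. Each subsequent line is one
# report record carrying the text, the token stream it was annotated
# against (token indices are tokenizer-dependent, so the file embeds them),
# and the facts as token-index intervals.
# ---------------------------------------------------------------------------

fact_to_record <- function(f) {
  list(type = f$fact_type,
       span = as.integer(f$fact_span),
       anchor = as.integer(f$anchor_span),
       modifiers = lapply(f$modifiers, function(m) {
         list(slot = m$slot, spans = lapply(m$spans, as.integer))
       }))
}

record_to_fact <- function(rec) {
  rf_fact(rec$type, unlist(rec$span), unlist(rec$anchor),
          modifiers = lapply(rec$modifiers, function(m) {
            list(slot = m$slot, spans = lapply(m$spans, unlist))
          }))
}

#' Read and write standoff annotation files
#'
#' The standoff dialect is line-delimited JSON: a versioned header line
#' naming the schema version and tokenizer identity, then one record per
#' report embedding the report text, its token stream, and its facts as
#' token-index intervals. `write_annotations()` followed by
#' `read_annotations()` is the identity on the in-memory representation.
#' Reading validates every record: token/text offset consistency, span
#' bounds, anchor-within-fact containment, and modifier interval ordering;
#' a malformed record raises an error naming the report id and record index.
#'
#' @param reports list of `rf_annotated` objects.
#' @param path file path.
#' @param schema_version schema version string recorded in the header.
#' @return `read_annotations()` returns a list of `rf_annotated`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(reports, path, schema_version = "1.0") {
  header <- jsonlite::toJSON(list(format = "radfacts-standoff",
                                  format_version = 1L,
                                  schema_version = schema_version,
                                  tokenizer = tokenizer_id),
                             auto_unbox = TRUE)
  lines <- vapply(reports, function(ar) {
    rec <- list(report_id = ar$report$report_id,
                text = ar$report$text,
                tokens = list(text = ar$report$tokens$text,
                              start = ar$report$tokens$start,
                              end = ar$report$tokens$end),
                metadata = ar$report$metadata,
                facts = lapply(ar$facts, fact_to_record))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(header), lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE)
  if (!identical(header$format, "radfacts-standoff")) {
    stop("not a radfacts standoff file (missing header): ", path, call. = FALSE)
  }
  lapply(seq_along(lines[-1]), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i + 1L]], simplifyVector = FALSE),
      error = function(e) stop("malformed record ", i, " in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    fail <- function(...) {
      stop("annotation record ", i, " (report_id '",
           rec$report_id %||% "?", "'): ", ..., call. = FALSE)
    }
    toks <- data.frame(
      index = seq_along(rec$tokens$text) - 1L,
      text = vapply(rec$tokens$text, as.character, character(1)),
      start = vapply(rec$tokens$start, as.integer, integer(1)),
      end = vapply(rec$tokens$end, as.integer, integer(1)),
      stringsAsFactors = FALSE)
    if (!identical(toks$text,
                   substring(rec$text, toks$start + 1L, toks$end))) {
      fail("token text does not match text at recorded offsets")
    }
    report <- structure(list(report_id = as.character(rec$report_id),
                             text = rec$text, tokens = toks,
                             metadata = rec$metadata %||% list()),
                        class = "rf_report")
    nt <- nrow(toks)
    facts <- lapply(rec$facts, record_to_fact)
    for (f in facts) {
      if (!is_interval(f$fact_span) || f$fact_span[2] > nt) {
        fail("fact span out of token range")
      }
      av <- as_interval_list(f$anchor_span)
      if (length(av) != 1L || !is_interval(av[[1]])) {
        fail("anchor span is not a single contiguous interval")
      }
      if (!interval_within(av[[1]], f$fact_span)) {
        fail("anchor span outside fact span")
      }
      for (m in f$modifiers) {
        if (!all(vapply(m$spans, is_interval, logical(1))) ||
            !intervals_sorted_disjoint(m$spans)) {
          fail("modifier slot '", m$slot, "' has invalid intervals")
        }
        if (!all(vapply(m$spans, interval_within, logical(1),
                        outer = f$fact_span))) {
          fail("modifier slot '", m$slot, "' outside fact span")
        }
      }
    }
    annotated_report(report, facts)
  })
}
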