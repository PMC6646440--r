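#' Word tokenization with character offsets
#'
#' Deterministic whitespace tokenizer that additionally splits leading and
#' trailing punctuation off each whitespace-delimited chunk (so
#' `"observed."` becomes `"observed"`, `"."` while interior punctuation as
#' in `"5.3"` or hyphenated terms stays attached). All annotation in this
#' package is at word-token granularity; offsets are 0-based, half-open
#' character positions into the original text, and every token's text equals
#' the substring of the report text at its offsets.
#'
#' The tokenizer is pluggable: any function with this signature and offset
#' contract can be passed to [tokenize_report()], and annotation files
#' record the tokenizer identity in their header.
#'
#' @param text a single character string (UTF-8).
#' @return a data.frame with columns `index` (0-based), `text`, `start`,
#'   `end`. Empty or all-whitespace text yields zero rows.
#' @examples
#' tokenize("No lesion observed.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(index = integer(0), text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out_text <- character(0); out_start <- integer(0)
  for (i in seq_along(starts)) {
    chunk <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    s0 <- starts[i] - 1L  # 0-based
    chars <- strsplit(chunk, "", fixed = TRUE)[[1]]
    n <- length(chars)
    lead <- 0L
    while (lead < n - 1L && grepl("^[[:punct:]]$", chars[lead + 1L])) {
      lead <- lead + 1L
    }
    trail <- 0L
    while (n - trail - lead > 1L && grepl("^[[:punct:]]$", chars[n - trail])) {
      trail <- trail + 1L
    }
    if (lead > 0L) {
      out_text <- c(out_text, chars[seq_len(lead)])
      out_start <- c(out_start, s0 + seq_len(lead) - 1L)
    }
    core_len <- n - lead - trail
    out_text <- c(out_text, substr(chunk, lead + 1L, lead + core_len))
    out_start <- c(out_start, s0 + lead)
    if (trail > 0L) {
      idx <- seq.int(n - trail + 1L, n)
      out_text <- c(out_text, chars[idx])
      out_start <- c(out_start, s0 + idx - 1L)
    }
  }
  data.frame(index = seq_along(out_text) - 1L, text = out_text,
             start = out_start, end = out_start + nchar(out_text),
             stringsAsFactors = FALSE)
}

tokenizer_id <- "radfacts-whitespace-punct-v1"

#' Tokenized report container
#'
#' @param text report text.
#' @param report_id identifier for the report.
#' @param metadata optional named list (modality, author role, ...).
#' @param tokenizer tokenizer function following the [tokenize()] contract.
#' @return an object of class `rf_report` with elements `report_id`, `text`,
#'   `tokens` (the offset data.frame) and `metadata`.
#' @export
tokenize_report <- function(text, report_id = "report", metadata = list(),
                            tokenizer = tokenize) {
  toks <- tokenizer(text)
  if (nrow(toks) > 0) {
    stopifnot(identical(toks$text,
                        substring(text, toks$start + 1L, toks$end)))
  }
  structure(list(report_id = as.character(report_id), text = text,
                 tokens = toks, metadata = metadata),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("<rf_report>", x$report_id, "-", nrow(x$tokens), "tokens\n")
  invisible(x)
}

n_tokens <- function(report) nrow(report$tokens)
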