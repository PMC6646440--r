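# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never disturb user-level randomness.
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) * 7919 + as.numeric(index) * 104729 + 11)
  as.integer(s %% 2147483629)
}

# --- token-interval helpers --------------------------------------------------
# Intervals are 0-based, half-open integer pairs c(start, end), start < end.

is_interval <- function(x) {
  is.numeric(x) && length(x) == 2L && !anyNA(x) &&
    x[1] == floor(x[1]) && x[2] == floor(x[2]) && x[1] >= 0 && x[1] < x[2]
}

# Normalise an interval or list of intervals into a list of integer pairs.
as_interval_list <- function(x) {
  if (is.numeric(x) && length(x) == 2L) x <- list(x)
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  lapply(x, function(iv) as.integer(iv))
}

interval_tokens <- function(iv) seq.int(iv[1], iv[2] - 1L)

intervals_tokens <- function(ivs) {
  if (length(ivs) == 0L) return(integer(0))
  unlist(lapply(ivs, interval_tokens), use.names = FALSE)
}

interval_within <- function(inner, outer) {
  inner[1] >= outer[1] && inner[2] <= outer[2]
}

# sorted + pairwise disjoint (touching allowed: [0,2),[2,3) is disjoint)
intervals_sorted_disjoint <- function(ivs) {
  if (length(ivs) <= 1L) return(TRUE)
  s <- vapply(ivs, `[`, numeric(1), 1L)
  e <- vapply(ivs, `[`, numeric(1), 2L)
  all(diff(s) > 0) && all(s[-1] >= e[-length(e)])
}

# --- numeric helpers ---------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# numerically stable binary cross-entropy from logits, elementwise mean
bce_from_logits <- function(logits, targets) {
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
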