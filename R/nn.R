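# Internal neural-network plumbing: parameter initialisation and Adam.
# Parameters are nested lists of numeric matrices/vectors; gradients mirror
# the same tree shape, so the optimizer walks both trees recursively.

unif_init <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

init_gru_layer <- function(input_dim, hidden) {
  k <- 1 / sqrt(hidden)
  one_dir <- function() list(Wx = unif_init(3 * hidden, input_dim, k),
                             Wh = unif_init(3 * hidden, hidden, k),
                             bx = stats::runif(3 * hidden, -k, k),
                             bh = stats::runif(3 * hidden, -k, k))
  list(fwd = one_dir(), bwd = one_dir())
}

init_bigru <- function(input_dim, hidden, layers) {
  out <- vector("list", layers)
  for (l in seq_len(layers)) {
    din <- if (l == 1) input_dim else 2 * hidden
    out[[l]] <- init_gru_layer(din, hidden)
  }
  out
}

init_linear <- function(din, dout) {
  k <- 1 / sqrt(din)
  list(W = unif_init(din, dout, k), b = stats::runif(dout, -k, k))
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(t = 0L, m = zeros_like(params), v = zeros_like(params))
}

# single recursive walk updating (param, m, v) from grad
adam_walk <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- adam_walk(p[[i]], g[[i]], m[[i]], v[[i]], lr_t, beta1, beta2, eps)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
  }
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- adam_walk(params, grads, state$m, state$v, lr_t, beta1, beta2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

add_bias_rows <- function(logits, b) {
  sweep(logits, 2L, b, "+")
}
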