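test_that("stage-1 forward yields probability matrices of the right shape", {
  sch <- tiny_schema()
  m <- stage1_init(sch, input_dim = 12, hidden = 8, seed = 3)
  E <- matrix(rnorm(10 * 12), 10, 12)
  out <- stage1_forward(m, E)
  expect_identical(dim(out$fact_scores), c(10L, 2L))
  expect_identical(dim(out$anchor_scores), c(10L, 2L))
  expect_true(all(out$fact_scores >= 0 & out$fact_scores <= 1))
  expect_error(stage1_forward(m, E[0, , drop = FALSE]), "empty document")
})

test_that("zeroed output heads score exactly 0.5 everywhere", {
  sch <- tiny_schema()
  m <- stage1_init(sch, input_dim = 6, hidden = 4, seed = 1)
  m$params$head_fact$W[] <- 0
  m$params$head_fact$b[] <- 0
  m$params$head_anchor$W[] <- 0
  m$params$head_anchor$b[] <- 0
  out <- stage1_forward(m, matrix(rnorm(24), 4, 6))
  expect_true(all(out$fact_scores == 0.5))
  expect_true(all(out$anchor_scores == 0.5))
})

test_that("evaluation-mode forward is deterministic; dropout acts only in training", {
  sch <- tiny_schema()
  m <- stage1_init(sch, input_dim = 6, hidden = 16, dropout = 0.5, seed = 2)
  E <- matrix(rnorm(60), 10, 6)
  expect_identical(stage1_forward(m, E)$fact_scores,
                   stage1_forward(m, E)$fact_scores)
  set.seed(1)
  a <- stage1_forward(m, E, training = TRUE)$fact_scores
  b <- stage1_forward(m, E, training = TRUE)$fact_scores
  expect_false(identical(a, b))
})

test_that("stage-1 gradients match finite differences", {
  sch <- tiny_schema()
  m <- stage1_init(sch, input_dim = 5, hidden = 3, dropout = 0, seed = 4)
  E <- matrix(rnorm(6 * 5), 6, 5)
  Yf <- matrix(rbinom(12, 1, 0.4), 6, 2)
  Ya <- matrix(rbinom(12, 1, 0.2), 6, 2)
  lg <- radfacts:::stage1_loss_grads(m, E, Yf, Ya)
  eps <- 1e-6
  check <- function(path_get, path_set, grad, k) {
    m2 <- m; m3 <- m
    p <- path_get(m)
    p2 <- p; p2[k] <- p[k] + eps
    p3 <- p; p3[k] <- p[k] - eps
    num <- (radfacts:::stage1_loss_grads(path_set(m2, p2), E, Yf, Ya)$loss -
              radfacts:::stage1_loss_grads(path_set(m3, p3), E, Yf, Ya)$loss) /
      (2 * eps)
    expect_lt(abs(num - grad[k]), 1e-5 * max(1, abs(num)))
  }
  set.seed(9)
  for (k in sample(length(m$params$head_fact$W), 4)) {
    check(function(m) m$params$head_fact$W,
          function(m, p) { m$params$head_fact$W <- p; m },
          lg$grads$head_fact$W, k)
  }
  for (k in sample(length(m$params$gru[[1]]$fwd$Wx), 4)) {
    check(function(m) m$params$gru[[1]]$fwd$Wx,
          function(m, p) { m$params$gru[[1]]$fwd$Wx <- p; m },
          lg$grads$gru[[1]]$fwd$Wx, k)
  }
})

test_that("decode_spans returns maximal threshold runs (worked examples)", {
  expect_identical(decode_spans(c(0.9, 0.9, 0.1, 0.8), 0.5),
                   list(c(0L, 2L), c(3L, 4L)))
  expect_identical(decode_spans(c(0.1, 0.2, 0.3), 0.5), list())
  expect_identical(decode_spans(c(0.9, 0.8, 0.7), 0.5), list(c(0L, 3L)))
  expect_identical(decode_spans(numeric(0), 0.5), list())
})

test_that("decode_spans equals the brute-force oracle on random vectors", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    scores <- round(runif(n), 2)
    th <- sample(c(0.3, 0.5, 0.7), 1)
    expect_identical(decode_spans(scores, th),
                     oracle_decode_spans(scores, th))
  }
})

test_that("candidate generation follows containment, type compatibility, minimality", {
  sch <- tiny_schema()
  # one fact span containing three anchors of its type -> three candidates
  cands <- generate_candidates(
    list(finding_observed = list(c(0, 12))),
    list(finding = list(c(1, 2), c(4, 5), c(8, 10))), sch)
  expect_length(cands, 3)
  expect_true(all(vapply(cands, function(x) identical(x$fact_span, c(0, 12)),
                         logical(1))))
  # anchor outside every fact span -> no candidate
  expect_length(generate_candidates(list(finding_observed = list(c(0, 3))),
                                    list(finding = list(c(5, 6))), sch), 0)
  # wrong anchor type for the enclosing fact span -> no candidate
  expect_length(generate_candidates(list(finding_observed = list(c(0, 8))),
                                    list(procedure = list(c(1, 2))), sch), 0)
  # nested fact spans -> smallest enclosing wins
  cands <- generate_candidates(
    list(finding_observed = list(c(0, 12), c(2, 6))),
    list(finding = list(c(3, 4))), sch)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$fact_span, c(2, 6))
})

test_that("candidate generation equals brute-force enumeration on random inputs", {
  sch <- tiny_schema()
  set.seed(62)
  for (i in 1:300) {
    rand_spans <- function(k) {
      lapply(seq_len(k), function(j) {
        s <- sample(0:10, 1); c(s, s + sample(1:5, 1))
      })
    }
    fact_spans <- list(finding_observed = rand_spans(sample(0:3, 1)),
                       had_procedure = rand_spans(sample(0:2, 1)))
    anchor_spans <- list(finding = rand_spans(sample(0:3, 1)),
                         procedure = rand_spans(sample(0:2, 1)))
    expect_identical(generate_candidates(fact_spans, anchor_spans, sch),
                     oracle_candidates(fact_spans, anchor_spans, sch))
  }
})
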