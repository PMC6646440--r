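test_that("candidate windows extend by the context and clip at edges", {
  E <- matrix(0, 200, 4)
  cand <- list(fact_type = "finding_observed", fact_span = c(30, 40),
               anchor_span = c(33, 35))
  inp <- build_candidate_input(cand, E, context = 20)
  expect_identical(inp$window, c(10L, 60L))
  expect_identical(inp$offsets, 10:59)
  # mask marks exactly the anchor positions (window rows 24-25, 1-based)
  expect_identical(which(inp$X[, 5] == 1), 24:25)
  # left-clipped window
  inp2 <- build_candidate_input(list(fact_type = "f", fact_span = c(5, 12),
                                     anchor_span = c(6, 7)), E, context = 20)
  expect_identical(inp2$window, c(0L, 32L))
  # window/offset round trip: offsets map window rows to document indices
  expect_identical(inp2$offsets[match(6, inp2$offsets)], 6L)
  expect_identical(inp$X[, 1:4], E[11:60, ])
})

test_that("parameter banks are separate per fact type", {
  sch <- tiny_schema()
  m <- stage2_init(sch, input_dim = 6, hidden = 5, seed = 2)
  expect_setequal(names(m$banks), fact_type_names(sch))
  X <- matrix(rnorm(8 * 7), 8, 7)
  inp1 <- list(X = X, offsets = 0:7, fact_type = "finding_observed")
  inp2 <- list(X = X, offsets = 0:7, fact_type = "had_procedure")
  o1 <- stage2_forward(m, inp1)
  o2 <- stage2_forward(m, inp2)
  expect_false(identical(o1$modifier_scores[, 1], o2$modifier_scores[, 1]))
  # modifier head width = declared slots + anchor refinement column
  expect_identical(ncol(o1$modifier_scores), 4L)  # 3 slots + 1
  expect_identical(ncol(o2$modifier_scores), 2L)  # 1 slot + 1
  expect_error(stage2_forward(m, list(X = X, offsets = 0:7,
                                      fact_type = "nope")), "no stage-2")
})

test_that("zeroed output heads give 0.5 modifier scores and uniform boundaries", {
  sch <- tiny_schema()
  m <- stage2_init(sch, input_dim = 4, hidden = 3, seed = 5)
  m$banks$finding_observed$head_mod$W[] <- 0
  m$banks$finding_observed$head_mod$b[] <- 0
  m$banks$finding_observed$head_span$W[] <- 0
  m$banks$finding_observed$head_span$b[] <- 0
  inp <- list(X = matrix(rnorm(30), 6, 5), offsets = 0:5,
              fact_type = "finding_observed")
  out <- stage2_forward(m, inp)
  expect_true(all(out$modifier_scores == 0.5))
  expect_true(all(out$begin_scores == 0))
  # uniform begin distribution over L -> cross-entropy = log(L)
  gold <- list(Y = matrix(0, 6, 4), begin = 2, end = 4)
  loss <- stage2_loss(out, gold)
  expect_equal(loss, log(2) + 2 * log(6), tolerance = 1e-12)
})

test_that("stage-2 loss equals a hand-computed sum of its three terms", {
  sch <- tiny_schema()
  m <- stage2_init(sch, input_dim = 4, hidden = 3, seed = 6)
  set.seed(7)
  inp <- list(X = matrix(rnorm(25), 5, 5), offsets = 3:7,
              fact_type = "had_procedure")
  out <- stage2_forward(m, inp)
  gold <- list(Y = matrix(rbinom(10, 1, 0.3), 5, 2), begin = 1, end = 5)
  # independent scalar arithmetic on the returned scores
  eps <- 1e-12
  bce <- -mean(gold$Y * log(out$modifier_scores + eps) +
                 (1 - gold$Y) * log(1 - out$modifier_scores + eps))
  soft <- function(x) exp(x) / sum(exp(x))
  ce_b <- -log(soft(out$span_logits[, 1])[gold$begin])
  ce_e <- -log(soft(out$span_logits[, 2])[gold$end])
  expect_equal(stage2_loss(out, gold), bce + ce_b + ce_e, tolerance = 1e-6)
  # perfect-confidence limit: loss approaches zero
  sure <- out
  sure$modifier_logits <- (gold$Y * 2 - 1) * 50
  sure$span_logits <- cbind(c(50, rep(-50, 4)), c(rep(-50, 4), 50))
  expect_lt(stage2_loss(sure, gold), 1e-8)
})

test_that("stage-2 gradients match finite differences", {
  sch <- tiny_schema()
  m <- stage2_init(sch, input_dim = 4, hidden = 3, seed = 8)
  set.seed(11)
  inp <- list(X = matrix(rnorm(30), 6, 5), offsets = 0:5,
              fact_type = "finding_observed")
  gold <- list(Y = matrix(rbinom(24, 1, 0.3), 6, 4), begin = 2, end = 5)
  lg <- radfacts:::stage2_loss_grads(m, inp, gold)
  eps <- 1e-6
  for (k in sample(length(m$banks$finding_observed$gru[[1]]$bwd$Wh), 5)) {
    m2 <- m; m3 <- m
    m2$banks$finding_observed$gru[[1]]$bwd$Wh[k] <-
      m$banks$finding_observed$gru[[1]]$bwd$Wh[k] + eps
    m3$banks$finding_observed$gru[[1]]$bwd$Wh[k] <-
      m$banks$finding_observed$gru[[1]]$bwd$Wh[k] - eps
    num <- (radfacts:::stage2_loss_grads(m2, inp, gold)$loss -
              radfacts:::stage2_loss_grads(m3, inp, gold)$loss) / (2 * eps)
    expect_lt(abs(num - lg$grads$gru[[1]]$bwd$Wh[k]), 1e-5 * max(1, abs(num)))
  }
})

test_that("refine_span decodes argmax boundaries with fallback and early ties", {
  off <- 10:19
  expect_identical(refine_span(c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
                               c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0),
                               off, c(0, 5)), c(12L, 18L))
  # end peak before begin peak -> fallback
  expect_identical(refine_span(c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
                               c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                               off, c(30, 40)), c(30L, 40L))
  # tied begin maxima -> earliest wins
  expect_identical(refine_span(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                               c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                               off, c(0, 5)), c(10L, 15L))
})

test_that("refine_span equals the brute-force oracle on random scores", {
  set.seed(63)
  for (i in 1:300) {
    L <- sample(2:15, 1)
    start <- sample(0:20, 1)
    off <- start:(start + L - 1)
    b <- sample(round(runif(L), 1))  # coarse grid to force ties
    e <- sample(round(runif(L), 1))
    fb <- c(start, start + L)
    expect_identical(refine_span(b, e, off, fb),
                     oracle_refine_span(b, e, off, fb))
  }
})

test_that("gold window labels align modifiers, anchor, and boundaries", {
  E <- matrix(0, 50, 3)
  f <- rf_fact("finding_observed", c(10, 20), c(12, 14),
               modifiers = list(negation = c(10, 11),
                                location = list(c(16, 18))))
  cand <- list(fact_type = f$fact_type, fact_span = f$fact_span,
               anchor_span = f$anchor_span)
  inp <- build_candidate_input(cand, E, context = 5)
  gold <- radfacts:::stage2_gold_labels(inp, f,
                                        c("negation", "location", "size"))
  expect_identical(inp$window, c(5L, 25L))
  expect_identical(which(gold$Y[, 1] == 1), 6L)          # negation at doc 10
  expect_identical(which(gold$Y[, 2] == 1), 12:13)       # location 16-17
  expect_identical(which(gold$Y[, 4] == 1), 8:9)         # anchor column
  expect_identical(inp$offsets[gold$begin], 10L)
  expect_identical(inp$offsets[gold$end] + 1L, 20L)
})
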