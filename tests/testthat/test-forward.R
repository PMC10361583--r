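test_that("attention-weighted distance matches hand-evaluated cases", {
  expect_equal(attn_distance(c(0, 0, 0), c(0, 0, 0), rand_simplex(3)), 0)
  expect_equal(attn_distance(c(0, 0), c(1, 1), c(1, 0)), 1.0)
  expect_equal(attn_distance(c(0, 0), c(1, 0.5), c(0.5, 0.5)), 0.75)
  expect_error(attn_distance(c(0, 0), c(1, 1, 1), c(0.5, 0.5)), "length")
  expect_error(attn_distance(c(0, 0), c(1, 1), c(0.5, 0.5), r_exponent = 0),
               "positive")
})

test_that("vectorised distances agree with the scalar definition", {
  set.seed(11)
  for (r in c(1, 2)) {
    pos <- matrix(runif(15), 5, 3)
    x <- runif(3)
    a <- rand_simplex(3)
    expect_equal(attn_distance_mat <- sustaind:::attn_distance_mat(pos, x, a, r),
                 apply(pos, 1, attn_distance, x, a, r))
  }
})

test_that("unit activation is zeta at zero distance and strictly decreasing", {
  expect_equal(unit_activation(0, 2), 2.0)
  expect_equal(unit_activation(1, 1), exp(-1))
  expect_lt(unit_activation(50, 2), 1e-10)
  d <- sort(runif(100, 0, 3))
  act <- unit_activation(d, 1.7)
  expect_true(all(diff(act) < 0))
  expect_error(unit_activation(-1, 2), "non-negative")
})

test_that("k-WTA returns the top-K eligible units and handles shortfalls", {
  expect_identical(select_winners(numeric(0), logical(0), 0.5, 0), integer(0))
  expect_identical(select_winners(c(3, 1, 2), rep(TRUE, 3), 2 / 3, 3),
                   c(1L, 3L))
  # fewer eligible than K: all returned
  act <- runif(5)
  expect_identical(select_winners(act, rep(TRUE, 5), 0.8, 10), 1:5)
  # no eligible units at all
  expect_identical(select_winners(act, rep(FALSE, 5), 0.5, 10), integer(0))
})

test_that("every selected winner outranks every non-winner (sort oracle)", {
  set.seed(21)
  for (i in 1:25) {
    m <- sample(5:50, 1)
    act <- runif(m)
    elig <- runif(m) > 0.3
    k_prop <- runif(1, 0.05, 0.9)
    w <- select_winners(act, elig, k_prop, m)
    K <- max(1L, round(k_prop * m))
    expect_length(w, min(K, sum(elig)))
    if (length(w) && sum(elig) > length(w)) {
      losers <- setdiff(which(elig), w)
      expect_gte(min(act[w]), max(act[losers]))
    }
    expect_true(all(elig[w]))
  }
})

test_that("tied activations resolve to the newest recruitment batch", {
  act <- c(1, 1, 1, 1)
  batch <- c(1L, 1L, 2L, 2L)
  w <- select_winners(act, rep(TRUE, 4), 0.5, 4, batch = batch)
  expect_identical(w, c(3L, 4L))
})

test_that("outputs are zero off the winner set", {
  expect_identical(unit_outputs(c(3, 1, 2), integer(0)), c(0, 0, 0))
  expect_identical(unit_outputs(c(3, 1, 2), c(1L, 3L)), c(3, 0, 2))
  out <- unit_outputs(runif(10), 4L)
  expect_identical(which(out != 0), 4L)
})

test_that("evidence is the weight-weighted sum of outputs", {
  expect_identical(decision_evidence(c(0, 0), matrix(1, 2, 2)), c(0, 0))
  w <- matrix(c(0.5, -0.5), 1, 2)
  expect_equal(decision_evidence(2, w), c(1, -1))
  # linearity: two co-located winners double the evidence
  w2 <- rbind(w, w)
  expect_equal(decision_evidence(c(2, 2), w2), 2 * decision_evidence(2, w))
  expect_error(decision_evidence(c(1, 2, 3), w), "nrow")
})

test_that("choice probabilities are a proper softmax, safe at extremes", {
  expect_equal(choice_probabilities(c(0, 0), 3), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(5, -2, 7), 0), rep(1 / 3, 3))
  p <- choice_probabilities(c(1, 0), 1)
  expect_equal(p, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # overflow-safe at |phi * evidence| up to 700
  for (e in list(c(700, 0), c(-700, 700), c(700, 699.5))) {
    p <- choice_probabilities(e, 1)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("forward pass on a fresh population yields uniform probabilities", {
  model <- new_population(tiny_params(), seed = 3L)
  fwd <- forward_pass(model, c(0, 1, 0))
  expect_length(fwd$winners, 0)
  expect_equal(fwd$probs, c(0.5, 0.5))
  expect_true(all(is.na(fwd$activations)))
})

test_that("a lone connected unit at the stimulus wins with activation zeta", {
  p <- tiny_params(n_units = 10L, k_prop = 0.1, zeta = 3)
  model <- manual_model(p, matrix(c(0, 1, 0), 1))
  fwd <- forward_pass(model, c(0, 1, 0))
  expect_identical(fwd$winners, 1L)
  expect_equal(fwd$activations[1], 3)
})

test_that("a zero attention weight masks its dimension completely", {
  p <- tiny_params(n_units = 12L, k_prop = 0.25)
  set.seed(5)
  model <- manual_model(p, matrix(runif(18), 6, 3),
                        weights = matrix(rnorm(12), 6, 2),
                        attention = c(0.5, 0.5, 0))
  f1 <- forward_pass(model, c(0.2, 0.7, 0.1))
  f2 <- forward_pass(model, c(0.2, 0.7, 0.9))
  expect_equal(f1$distances, f2$distances)
  expect_identical(f1$winners, f2$winners)
  expect_equal(f1$probs, f2$probs)
})

test_that("lesioned units never win and contribute nothing to evidence", {
  p <- tiny_params(n_units = 10L, k_prop = 0.5)
  set.seed(7)
  model <- manual_model(p, matrix(runif(30), 10, 3),
                        weights = matrix(rnorm(20), 10, 2))
  model$lesioned[c(1, 2)] <- TRUE
  fwd <- forward_pass(model, c(0.5, 0.5, 0.5))
  expect_false(any(c(1L, 2L) %in% fwd$winners))
  expect_true(all(is.na(fwd$activations[1:2])))
  # evidence equals the winner-only sum, so lesioned rows are excluded
  expect_equal(fwd$evidence,
               as.vector(crossprod(model$weights, fwd$outputs)))
  expect_equal(fwd$outputs[1:2], c(0, 0))
})

test_that("a duplicated population produces identical choice probabilities", {
  p <- tiny_params(n_units = 6L, k_prop = 0.5)
  set.seed(9)
  pos <- matrix(runif(9), 3, 3)
  wts <- matrix(rnorm(6), 3, 2)
  m1 <- manual_model(p, pos, weights = wts)
  p2 <- tiny_params(n_units = 12L, k_prop = 0.5)
  m2 <- manual_model(p2, rbind(pos, pos), weights = rbind(wts, wts) / 2)
  f1 <- forward_pass(m1, c(0.1, 0.9, 0.4))
  f2 <- forward_pass(m2, c(0.1, 0.9, 0.4))
  expect_equal(f1$probs, f2$probs, tolerance = 1e-12)
})
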