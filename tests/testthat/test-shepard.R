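test_that("all six structures are balanced over all eight stimuli", {
  for (pt in 1:6) {
    s <- shepard_structure(pt)
    expect_equal(nrow(unique(s$stimuli)), 8L)
    expect_equal(as.integer(table(s$labels)), c(4L, 4L))
  }
  expect_error(shepard_structure(7), "I-VI")
  expect_identical(shepard_structure("IV")$labels, shepard_structure(4)$labels)
})

test_that("type I is one-feature separable and type VI is pure parity", {
  s1 <- shepard_structure(1)
  expect_identical(s1$labels, ifelse(s1$stimuli[, 1] == 0, 1L, 2L))
  s6 <- shepard_structure(6)
  # exhaustive check: no single feature or feature pair carries any
  # information about the label (conditional label distribution is 50/50)
  for (js in list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3))) {
    cell <- apply(s6$stimuli[, js, drop = FALSE], 1, paste, collapse = "")
    tab <- table(cell, s6$labels)
    expect_true(all(tab[, 1] == tab[, 2]))
  }
  expect_identical(s6$labels,
                   ifelse(rowSums(s6$stimuli) %% 2 == 0, 1L, 2L))
})

test_that("trial sequences are seeded blocks with two repetitions each", {
  s <- shepard_structure(3)
  a <- make_trial_sequence(s, 3, 99L)
  b <- make_trial_sequence(s, 3, 99L)
  expect_identical(a, b)
  d <- make_trial_sequence(s, 3, 100L)
  expect_false(identical(a$stimuli, d$stimuli))
  for (blk in 1:3) {
    rows <- a$stimuli[(blk - 1) * 16 + 1:16, ]
    key <- apply(rows, 1, paste, collapse = "")
    expect_true(all(table(key) == 2L))
  }
})

test_that("error curves average 1 - P(correct) per block across runs", {
  fake <- list(list(prob_correct = rep(1, 32)))
  expect_equal(error_curve(fake, n_keep = 2), c(0, 0))
  probs <- runif(32)
  one <- list(list(prob_correct = probs))
  expect_equal(error_curve(one, n_keep = 2),
               c(mean(1 - probs[1:16]), mean(1 - probs[17:32])))
  two <- list(list(prob_correct = probs), list(prob_correct = 1 - probs))
  expect_equal(error_curve(two, n_keep = 2), c(0.5, 0.5))
})

test_that("the first trial contributes chance-level error", {
  p <- tiny_params(n_units = 40L, k_prop = 0.1)
  rec <- train_on_problem(p, shepard_structure(1), 1, 5L)[[1]]
  expect_equal(rec$prob_correct[1], 0.5)
})

test_that("a frozen model stays at chance; an adequate one learns", {
  s <- shepard_structure(1)
  frozen <- tiny_params(n_units = 40L, k_prop = 0.1, eta_pos = 0,
                        eta_group = 0, eta_attn = 0, eta_cweights = 0)
  # a frozen model errs (ties) on every trial, so it keeps recruiting until
  # the unit pool is exhausted — the warnings are expected here
  rec <- suppressWarnings(train_on_problem(frozen, s, 2, 1L))[[1]]
  expect_true(all(rec$prob_correct == 0.5))
  live <- tiny_params(n_units = 40L, k_prop = 0.1)
  curve <- error_curve(train_on_problem(live, s, 8, 1:3), n_keep = 8)
  expect_lt(curve[8], curve[1])
  expect_length(train_on_problem(live, s, 2, 1:25), 25L)
})

test_that("flock counting matches recruitment structure in noiseless runs", {
  p <- tiny_params(n_units = 60L, k_prop = 0.05)
  model <- new_population(p, seed = 2L)
  expect_equal(count_flocks(model), 0L)
  model <- recruit_units(model, c(0, 0, 0))$model
  expect_equal(count_flocks(model), 1L)
  model <- recruit_units(model, c(1, 1, 1))$model
  expect_equal(count_flocks(model), 2L)
  # flocks closer than the linkage threshold on every attended dimension
  # merge into one virtual cluster
  model$attention <- c(0.98, 0.01, 0.01)
  model2 <- recruit_units(model, c(0, 1, 1))$model  # differs on ignored dims
  expect_equal(count_flocks(model2), 2L)
})

test_that("grid search recovers the generating parameters (self-recovery)", {
  p <- tiny_params(n_units = 60L, k_prop = 0.05, eta_cweights = 0.05)
  seeds <- 1:2
  ref <- model_curves(p, seeds, problems = c(1, 6), n_blocks = 4L)
  fit <- fit_parameters(ref, grid_spec = list(phi = c(1, 2, 4)),
                        seeds = seeds, base_params = p,
                        problems = c(1, 6), refine = FALSE)
  expect_equal(fit$best_params$phi, 2)
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  # size-one grid returns that point; larger grids never do worse
  fit1 <- fit_parameters(ref, list(phi = 3), seeds, p, c(1, 6),
                         refine = FALSE)
  expect_equal(fit1$best_params$phi, 3)
  expect_gte(fit1$sse, fit$sse)
  expect_error(fit_parameters(ref, list(), seeds, p), "at least one")
})

test_that("refinement stage searches around the incumbent", {
  p <- tiny_params(n_units = 60L, k_prop = 0.05, eta_cweights = 0.05)
  seeds <- 1L
  ref <- model_curves(p, seeds, problems = 1, n_blocks = 3L)
  fit <- fit_parameters(ref, list(phi = c(1, 3)), seeds, p, problems = 1,
                        refine = TRUE)
  expect_true(any(fit$grid_evaluations$stage == 2))
  expect_equal(fit$best_params$phi, 2)  # refined midpoint hits the truth
})
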