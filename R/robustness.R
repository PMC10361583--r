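#' Gaussian update noise
#'
#' Adds an independent zero-mean Gaussian draw (SD `sd` per feature
#' dimension) to each winner's net position displacement for the trial.
#' Because each winner receives its own draw, the flocking contraction
#' averages the noise across the `K` winners, which is why larger
#' populations tolerate noise better.
#'
#' @param displacements K x n matrix of net position displacements.
#' @param sd non-negative noise SD per dimension.
#' @return K x n matrix with noise added.
#' @export
apply_update_noise <- function(displacements, sd) {
  if (sd < 0) stop("`sd` must be non-negative")
  if (sd == 0) return(displacements)
  displacements + matrix(stats::rnorm(length(displacements), 0, sd),
                         nrow = nrow(displacements))
}

#' Lesion specification
#'
#' @param trial trial index at which the lesion event occurs (applied at the
#'   start of that trial).
#' @param n_remove number of connected units to remove permanently.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(trial, n_remove) {
  stopifnot(trial >= 1, n_remove >= 0)
  structure(list(trial = as.integer(trial), n_remove = as.integer(n_remove)),
            class = "lesion_spec")
}

#' Apply a lesion event
#'
#' Uniformly samples `min(n_remove, #connected)` connected units and marks
#' them lesioned: from that point on they never win, output, or update.
#' Their weights are frozen at pre-lesion values but contribute zero
#' evidence.
#'
#' @param model a `sustain_model`.
#' @param spec a [lesion_spec()].
#' @return the updated model.
#' @export
apply_lesion <- function(model, spec) {
  if (spec$n_remove == 0L) return(model)
  pool <- which(model$connected & !model$lesioned)
  if (length(pool) == 0L) return(model)
  n <- min(spec$n_remove, length(pool))
  hit <- if (length(pool) == 1L) pool else sample(pool, n)
  model$lesioned[hit] <- TRUE
  model
}

#' Full-factorial robustness sweep
#'
#' Crosses problem types, population sizes, recurrence strengths, noise
#' levels and lesion counts, trains the model over the given seeds in every
#' cell, and returns a tidy per-block results table.
#'
#' @param problem_types integer vector of Shepard types (1-6).
#' @param n_units_grid integer vector of population sizes.
#' @param eta_group_grid numeric vector of recurrence strengths.
#' @param noise_sds numeric vector of update-noise SDs.
#' @param lesion_ns integer vector of lesion counts (0 = control).
#' @param seeds integer vector of run seeds.
#' @param base_params parameter template; `n_units` and `eta_group` are
#'   overridden per cell.
#' @param n_blocks blocks per run.
#' @param lesion_trial trial of the single lesion event.
#' @return data.frame with columns problem, n_units, eta_group, noise_sd,
#'   lesion_n, seed, block, error.
#' @export
robustness_sweep <- function(problem_types = 1L, n_units_grid = c(20L, 1000L),
                             eta_group_grid = 1, noise_sds = 0,
                             lesion_ns = 0L, seeds = 1:5,
                             base_params = default_shepard_params(),
                             n_blocks = 16L, lesion_trial = 60L) {
  rows <- list()
  for (pt in problem_types) {
    structure <- shepard_structure(pt)
    for (nu in n_units_grid) for (eg in eta_group_grid) {
      params <- base_params
      params$n_units <- as.integer(nu)
      params$eta_group <- eg
      for (sdv in noise_sds) for (ln in lesion_ns) {
        lesion <- if (ln > 0) lesion_spec(lesion_trial, ln) else NULL
        for (sd_i in seq_along(seeds)) {
          rec <- train_on_problem(params, structure, n_blocks,
                                  seeds[sd_i], noise_sd = sdv,
                                  lesion = lesion)[[1]]
          err <- error_curve(list(rec), n_keep = n_blocks)
          rows[[length(rows) + 1L]] <- data.frame(
            problem = pt, n_units = nu, eta_group = eg, noise_sd = sdv,
            lesion_n = ln, seed = seeds[sd_i],
            block = seq_along(err), error = err)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Prototype-model baseline
#'
#' A degenerate comparator with exactly one unit per category label. Each
#' unit is recruited at the stimulus on the first encounter of its label and
#' thereafter tracks its category centroid via a supervised Kohonen update
#' (no flocking, fixed uniform attention). Both prototypes contribute
#' evidence and connection weights learn by cross-entropy as usual. The
#' baseline learns linearly separable problems (type I) but stays at chance
#' on exclusive-or structure (type II), where the two category centroids
#' coincide at the centre of the cube.
#'
#' @param structure a [shepard_structure()].
#' @param params parameter template (`zeta`, `phi`, `eta_pos`,
#'   `eta_cweights` are used).
#' @param n_blocks number of 16-trial blocks.
#' @param seeds integer vector of run seeds.
#' @return list with `curve` (per-block error) and `records` (per-run
#'   prob-correct vectors and final prototype positions).
#' @export
prototype_baseline <- function(structure, params = default_shepard_params(),
                               n_blocks = 16L, seeds = 1L) {
  z <- params$n_decisions
  n <- params$n_features
  records <- lapply(seeds, function(seed) {
    seq <- make_trial_sequence(structure, n_blocks, as.integer(seed))
    pos <- matrix(NA_real_, nrow = z, ncol = n)
    weights <- matrix(0, nrow = z, ncol = z)
    attention <- rep(1 / n, n)
    n_trials <- nrow(seq$stimuli)
    probs <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      x <- seq$stimuli[t, ]
      lab <- seq$labels[t]
      if (any(is.na(pos[lab, ]))) pos[lab, ] <- x
      live <- which(!is.na(pos[, 1]))
      d <- attn_distance_mat(pos[live, , drop = FALSE], x, attention,
                             params$r_exponent)
      act <- unit_activation(d, params$zeta)
      evidence <- colSums(weights[live, , drop = FALSE] * act)
      pr <- choice_probabilities(evidence, params$phi)
      probs[t] <- pr[lab]
      # supervised prototype update: the correct label's unit tracks its
      # category centroid
      pos[lab, ] <- pos[lab, ] + params$eta_pos * (x - pos[lab, ])
      one_hot <- numeric(z); one_hot[lab] <- 1
      weights[live, ] <- weights[live, ] +
        params$eta_cweights * outer(act, (one_hot - pr) * params$phi)
    }
    list(prob_correct = probs, positions = pos)
  })
  curve_records <- lapply(records, function(r) list(prob_correct = r$prob_correct))
  list(curve = error_curve(curve_records, n_keep = n_blocks),
       records = records)
}
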