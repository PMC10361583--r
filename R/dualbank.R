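#' Parameters for the anterior/posterior dual-bank model
#'
#' Two unit pools that differ only in receptive-field breadth: the anterior
#' bank has broader tuning (lower `zeta`) than the posterior bank. Each bank
#' carries its own full parameter set (including its own `phi`, which acts
#' as a per-bank evidence gain inside the single shared softmax), giving the
#' twelve free parameters of the dual model.
#'
#' @param anterior [sustain_params()] for the anterior (broadly tuned) bank.
#' @param posterior [sustain_params()] for the posterior (narrowly tuned)
#'   bank; must satisfy `anterior$zeta < posterior$zeta`.
#' @return a `dual_params` list.
#' @export
dual_params <- function(anterior, posterior) {
  stopifnot(inherits(anterior, "sustain_params"),
            inherits(posterior, "sustain_params"))
  if (!(anterior$zeta < posterior$zeta)) {
    stop("anterior bank must be more broadly tuned: anterior$zeta < posterior$zeta")
  }
  if (anterior$n_decisions != posterior$n_decisions ||
      anterior$n_features != posterior$n_features) {
    stop("banks must share feature and decision dimensions")
  }
  structure(list(anterior = anterior, posterior = posterior),
            class = "dual_params")
}

#' Create a fresh dual-bank model
#'
#' @param params a [dual_params()] object.
#' @param seed integer seed for unit placement (both banks draw from it).
#' @return a `sustain_dual` list with `anterior` and `posterior`
#'   `sustain_model` states.
#' @export
new_dual_population <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ant <- new_population(params$anterior)
  post <- new_population(params$posterior)
  structure(list(anterior = ant, posterior = post), class = "sustain_dual")
}

#' Forward pass of the dual-bank model
#'
#' k-WTA is applied within each bank separately; each bank's evidence is
#' scaled by its own `phi` gain and the two contributions are summed into
#' the combined evidence that feeds a single softmax. Per-bank evidence is
#' recorded, so the combined evidence is exactly the sum of the bank
#' evidences.
#'
#' @param dual a `sustain_dual` model.
#' @param stimulus stimulus location.
#' @return list with `probs`, `evidence` (combined), `by_bank` (2 x z
#'   matrix of per-bank scaled evidence), and the per-bank forward results.
#' @export
dual_forward <- function(dual, stimulus) {
  fa <- forward_pass(dual$anterior, stimulus)
  fp <- forward_pass(dual$posterior, stimulus)
  ev_a <- dual$anterior$params$phi * fa$evidence
  ev_p <- dual$posterior$params$phi * fp$evidence
  evidence <- ev_a + ev_p
  probs <- choice_probabilities(evidence, 1)
  by_bank <- rbind(anterior = ev_a, posterior = ev_p)
  list(probs = probs, evidence = evidence, by_bank = by_bank,
       anterior = fa, posterior = fp)
}

# weight update for one bank driven by the shared combined probabilities
dual_bank_learn <- function(model, fwd, stimulus, probs, target) {
  p <- model$params
  w <- fwd$winners
  if (length(w) == 0L) return(model)
  active <- which(eligible_units(model))
  new_attention <- attention_update(model$attention, model, stimulus,
                                    fwd$activations, w, active)
  new_weights <- weight_update(model$weights, fwd$outputs, probs,
                               target, p$phi, p$eta_cweights, w)
  P0 <- model$positions[w, , drop = FALSE]
  P1 <- kohonen_update(P0, stimulus, p$eta_pos)
  P2 <- flock_update(P1, p$eta_group)
  model$positions[w, ] <- P2
  model$attention <- new_attention
  model$weights <- new_weights
  model
}

#' Train the dual-bank model on a Shepard problem
#'
#' Both banks form flocks independently (own recruitment, positions,
#' attention) and are linked only through the shared category response:
#' recruitment is triggered by the combined output (first trial, or combined
#' evidence for the correct category not strictly maximal), and both banks'
#' connection weights descend the cross-entropy of the shared combined
#' probabilities. The bank better suited to a problem takes over by
#' developing larger connection weights.
#'
#' @param params a [dual_params()] object.
#' @param structure a [shepard_structure()].
#' @param n_blocks number of 16-trial blocks.
#' @param seeds integer vector of run seeds.
#' @return list of run records with `prob_correct`, `weight_mass` (2 x
#'   n_trials matrix of summed absolute connection weights per bank),
#'   `bank_prob_correct` (2 x n_trials standalone per-bank correct-category
#'   probability), and the final `dual` state.
#' @export
dual_train <- function(params, structure, n_blocks, seeds) {
  lapply(seeds, function(seed) {
    seed <- as.integer(seed) %% 2147480000L
    seq <- make_trial_sequence(structure, n_blocks, seed)
    dual <- new_dual_population(params, seed = (seed + 500003L) %% 2147480000L)
    n_trials <- nrow(seq$stimuli)
    probs <- numeric(n_trials)
    wmass <- matrix(0, 2, n_trials, dimnames = list(c("anterior", "posterior"), NULL))
    bprob <- matrix(0, 2, n_trials, dimnames = list(c("anterior", "posterior"), NULL))
    for (t in seq_len(n_trials)) {
      x <- seq$stimuli[t, ]
      lab <- seq$labels[t]
      fwd <- dual_forward(dual, x)
      first <- !any(dual$anterior$connected) && !any(dual$posterior$connected)
      if (should_recruit(fwd$evidence, lab, is_first_trial = first)) {
        dual$anterior <- recruit_units(dual$anterior, x)$model
        dual$posterior <- recruit_units(dual$posterior, x)$model
        fwd <- dual_forward(dual, x)
      }
      probs[t] <- fwd$probs[lab]
      bprob[1, t] <- choice_probabilities(fwd$by_bank[1, ], 1)[lab]
      bprob[2, t] <- choice_probabilities(fwd$by_bank[2, ], 1)[lab]
      dual$anterior <- dual_bank_learn(dual$anterior, fwd$anterior, x,
                                       fwd$probs, lab)
      dual$posterior <- dual_bank_learn(dual$posterior, fwd$posterior, x,
                                        fwd$probs, lab)
      dual$anterior$trial <- dual$anterior$trial + 1L
      dual$posterior$trial <- dual$posterior$trial + 1L
      wmass[1, t] <- sum(abs(dual$anterior$weights))
      wmass[2, t] <- sum(abs(dual$posterior$weights))
    }
    list(prob_correct = probs, weight_mass = wmass,
         bank_prob_correct = bprob, dual = dual, seed = seed)
  })
}

#' Blocks to criterion for per-bank standalone accuracy
#'
#' Number of 16-trial blocks before a bank's standalone correct-category
#' probability first reaches `criterion` as a block average (`Inf` when the
#' criterion is never reached).
#'
#' @param records result of [dual_train()].
#' @param bank `"anterior"` or `"posterior"`.
#' @param criterion block-mean probability threshold.
#' @param block_size trials per block.
#' @return mean number of blocks to criterion across runs.
#' @export
bank_blocks_to_criterion <- function(records, bank = "posterior",
                                     criterion = 0.9, block_size = 16L) {
  per_run <- vapply(records, function(rec) {
    p <- rec$bank_prob_correct[bank, ]
    n_blocks <- length(p) %/% block_size
    bm <- colMeans(matrix(p[seq_len(n_blocks * block_size)],
                          nrow = block_size))
    hit <- which(bm >= criterion)
    if (length(hit)) hit[1] else Inf
  }, numeric(1))
  mean(per_run)
}
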