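#' Kohonen position update
#'
#' Moves each winner toward the current stimulus:
#' `pos_i <- pos_i + eta * (x - pos_i)`. With `eta = 1` winners land exactly
#' on the stimulus; with `eta = 0` positions are unchanged.
#'
#' @param positions K x n matrix of winner positions.
#' @param stimulus stimulus location (length n).
#' @param eta non-negative learning rate.
#' @return updated K x n matrix.
#' @export
kohonen_update <- function(positions, stimulus, eta) {
  if (eta < 0) stop("`eta` must be non-negative")
  positions + eta * (rep(stimulus, each = nrow(positions)) - positions)
}

#' Recurrent flocking update
#'
#' Moves each winner toward the centroid of the winners' positions:
#' `pos_i <- pos_i + eta_group * (group - pos_i)` where `group` is the mean
#' winner position. The centroid itself is exactly preserved, and for
#' `eta_group` in `[0, 1]` the winner set contracts (pairwise distances are
#' non-increasing). With `eta_group = 1` all winners collapse onto the
#' centroid, which is what welds co-activated units into a virtual cluster.
#'
#' @param positions K x n matrix of winner positions (after the Kohonen step).
#' @param eta_group recurrent rate in `[0, 1]`.
#' @return updated K x n matrix.
#' @export
flock_update <- function(positions, eta_group) {
  if (eta_group < 0) stop("`eta_group` must be non-negative")
  K <- nrow(positions)
  if (K <= 1L || eta_group == 0) return(positions)
  centroid <- colMeans(positions)
  positions + eta_group * (rep(centroid, each = K) - positions)
}

#' Analytic attention gradient
#'
#' Gradient, with respect to the attention weights, of the summed activation
#' of the winners minus the summed activation of the non-winner active units.
#' For `r = 1` each unit contributes
#' `d act_i / d a_j = -zeta^2 * exp(-zeta * dist_i) * |pos_ij - x_j|`
#' (subgradient 0 where the unit matches the stimulus on dimension j), so
#' attention grows on dimensions where winners match the stimulus and losers
#' do not.
#'
#' @param model a `sustain_model`.
#' @param stimulus stimulus location.
#' @param activations full-length activation vector from the forward pass.
#' @param winners winner indices.
#' @param active indices of all active (connected, non-lesioned) units.
#' @return length-n gradient vector.
#' @export
attention_gradient <- function(model, stimulus, activations, winners, active) {
  p <- model$params
  n <- p$n_features
  if (length(active) == 0L) return(numeric(n))
  D <- abs(model$positions[active, , drop = FALSE] -
             rep(stimulus, each = length(active)))
  act <- activations[active]
  sgn <- ifelse(active %in% winners, 1, -1)
  if (p$r_exponent == 1) {
    # d act/d a_j = -zeta * act_i * |pos_ij - x_j|
    as.vector(crossprod(D, -p$zeta * act * sgn))
  } else {
    r <- p$r_exponent
    S <- as.vector(D^r %*% model$attention)     # dist^r
    dist <- S^(1 / r)
    ddist <- matrix(0, nrow = length(active), ncol = n)
    pos_S <- S > 0
    if (any(pos_S)) {
      ddist[pos_S, ] <- (1 / r) * S[pos_S]^(1 / r - 1) *
        D[pos_S, , drop = FALSE]^r
    }
    as.vector(crossprod(ddist, -p$zeta * act * sgn))
  }
}

#' Attention update with simplex projection
#'
#' Applies gradient ascent `a <- a + (eta_attn / n_active) * g` on the
#' winner-minus-loser summed activation, then projects back onto the simplex
#' by clipping negative entries to zero and renormalising to sum 1. If the
#' clipped vector is all-zero the attention is reset to uniform with a
#' warning. Dividing the gradient by the number of active units keeps the
#' attention trajectory independent of population size.
#'
#' @inheritParams attention_gradient
#' @param attention current attention weights.
#' @return updated attention weights (non-negative, summing to 1).
#' @export
attention_update <- function(attention, model, stimulus, activations,
                             winners, active) {
  p <- model$params
  if (p$eta_attn == 0 || length(active) == 0L) return(attention)
  g <- attention_gradient(model, stimulus, activations, winners, active)
  a <- attention + (p$eta_attn / length(active)) * g
  a[a < 0] <- 0
  s <- sum(a)
  if (s <= 0) {
    warning("attention collapsed to zero after clipping; reset to uniform")
    return(rep(1 / length(a), length(a)))
  }
  a / s
}

#' Connection-weight update (cross-entropy descent)
#'
#' Gradient descent on the cross-entropy loss of the softmax output against a
#' one-hot target: `dw_ij = (eta_cweights / K) * (target_j - prob_j) * phi *
#' out_i`. Only winner rows change (losers have zero output, hence zero
#' gradient), and never-connected units' weights stay exactly zero. Division
#' by the winner count `K` keeps aggregate evidence scale-invariant.
#'
#' @param weights m x z weight matrix.
#' @param outputs length-m output vector.
#' @param probs length-z probability vector from the forward pass.
#' @param target integer target label in `1..z`.
#' @param phi decision certainty used in the softmax.
#' @param eta_cweights learning rate.
#' @param winners winner indices (the rows allowed to change).
#' @return updated weight matrix.
#' @export
weight_update <- function(weights, outputs, probs, target, phi,
                          eta_cweights, winners) {
  if (length(winners) == 0L || eta_cweights == 0) return(weights)
  z <- ncol(weights)
  one_hot <- numeric(z)
  one_hot[target] <- 1
  K <- length(winners)
  delta <- outer(outputs[winners], (one_hot - probs) * phi) *
    (eta_cweights / K)
  weights[winners, ] <- weights[winners, , drop = FALSE] + delta
  weights
}

#' Recruitment trigger
#'
#' Recruitment occurs on the first trial (no connected units, hence no
#' output) or when the model errs: the evidence for the correct category is
#' not strictly the maximum. Ties count as errors, so the model cannot stall
#' at exact symmetry; evidence differences within a tiny relative band are
#' treated as ties so that knife-edge decisions resolve identically across
#' population sizes (the scale-invariance contract).
#'
#' @param evidence length-z evidence vector from the forward pass.
#' @param target integer target label in `1..z`.
#' @param is_first_trial logical; `TRUE` when no units are connected yet.
#' @param tol relative tolerance of the tie band.
#' @return logical.
#' @export
should_recruit <- function(evidence, target, is_first_trial = FALSE,
                           tol = 1e-9) {
  if (is_first_trial) return(TRUE)
  eps <- tol * max(1, abs(evidence))
  evidence[target] <= max(evidence[-target]) + eps
}

#' Recruit units at the current stimulus
#'
#' Selects the `K` unconnected, non-lesioned units nearest to the stimulus
#' (attention-weighted distance), marks them connected, and snaps their
#' positions exactly to the stimulus position, so the recruits form a
#' co-located nascent flock with maximal activation. If fewer than `K`
#' unconnected units remain, all of them are recruited with a warning; with
#' none available recruitment is a no-op with a warning.
#'
#' @param model a `sustain_model`.
#' @param stimulus stimulus location.
#' @param K number of units to recruit (defaults to the model's winner count).
#' @return list with the updated `model` and `recruited` index vector.
#' @export
recruit_units <- function(model, stimulus, K = n_winners(model$params)) {
  if (K < 1L) stop("`K` must be at least 1")
  pool <- which(!model$connected & !model$lesioned)
  if (length(pool) == 0L) {
    warning("no unconnected units available; recruitment skipped")
    return(list(model = model, recruited = integer(0)))
  }
  if (length(pool) < K) {
    warning(sprintf("only %d unconnected units remain (requested %d)",
                    length(pool), K))
    chosen <- pool
  } else {
    d <- attn_distance_mat(model$positions[pool, , drop = FALSE],
                           stimulus, model$attention,
                           model$params$r_exponent)
    chosen <- pool[order(d, pool)[seq_len(K)]]
  }
  model$n_events <- model$n_events + 1L
  model$connected[chosen] <- TRUE
  model$batch[chosen] <- model$n_events
  model$positions[chosen, ] <- rep(stimulus, each = length(chosen))
  list(model = model, recruited = chosen)
}

#' One supervised learning trial
#'
#' Runs the full per-trial loop: (1) forward pass; (2) recruitment when the
#' first trial or an error triggers it, followed by a fresh forward pass so
#' the recruits can win and learn on their trigger trial; (3) Kohonen update
#' of the winners toward the stimulus; (4) recurrent flocking update toward
#' the winners' centroid; (5) optional zero-mean Gaussian noise added to each
#' winner's net position displacement; (6) attention update; (7)
#' connection-weight update. The recorded choice probability is the one the
#' learning updates act on (the post-recruitment forward pass).
#'
#' @param model a `sustain_model`.
#' @param stimulus stimulus location.
#' @param target integer target label in `1..z`.
#' @param noise_sd non-negative SD of the Gaussian learning noise.
#' @param noise_mode `"update"` (default) perturbs each winner's net
#'   displacement; `"positions"` instead perturbs every active unit's
#'   position once per trial, before the forward pass.
#' @return list with updated `model`, the `forward` result used for learning,
#'   `recruited` indices, and `prob_correct`.
#' @export
training_step <- function(model, stimulus, target, noise_sd = 0,
                          noise_mode = c("update", "positions")) {
  p <- model$params
  noise_mode <- match.arg(noise_mode)
  if (noise_sd > 0 && noise_mode == "positions") {
    active <- which(eligible_units(model))
    if (length(active)) {
      model$positions[active, ] <-
        apply_update_noise(model$positions[active, , drop = FALSE], noise_sd)
    }
  }
  fwd <- forward_pass(model, stimulus)
  recruited <- integer(0)
  first <- !any(model$connected)
  if (should_recruit(fwd$evidence, target, is_first_trial = first)) {
    rec <- recruit_units(model, stimulus)
    model <- rec$model
    recruited <- rec$recruited
    if (length(recruited)) fwd <- forward_pass(model, stimulus)
  }
  w <- fwd$winners
  if (length(w)) {
    # attention and weight updates consume the forward-pass configuration,
    # so compute them from the pre-move positions before writing the new ones
    active <- which(eligible_units(model))
    new_attention <- attention_update(model$attention, model, stimulus,
                                      fwd$activations, w, active)
    new_weights <- weight_update(model$weights, fwd$outputs, fwd$probs,
                                 target, p$phi, p$eta_cweights, w)
    P0 <- model$positions[w, , drop = FALSE]
    P1 <- kohonen_update(P0, stimulus, p$eta_pos)
    P2 <- flock_update(P1, p$eta_group)
    disp <- P2 - P0
    if (noise_sd > 0 && noise_mode == "update") {
      disp <- apply_update_noise(disp, noise_sd)
    }
    model$positions[w, ] <- P0 + disp
    model$attention <- new_attention
    model$weights <- new_weights
  }
  model$trial <- model$trial + 1L
  list(model = model, forward = fwd, recruited = recruited,
       prob_correct = fwd$probs[target])
}
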