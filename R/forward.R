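#' Attention-weighted distance between a unit and a stimulus
#'
#' Computes `[sum_j a_j * |pos_j - x_j|^r]^(1/r)`. With `r = 1` (the default
#' used for separable-dimension stimuli) this is the attention-weighted
#' city-block distance. Attention weights are non-negative and sum to 1, so
#' a zero weight masks its dimension entirely.
#'
#' @param position numeric vector, unit position in feature space.
#' @param stimulus numeric vector, stimulus location (same length).
#' @param attention numeric vector of attention weights (same length).
#' @param r_exponent positive distance exponent.
#' @return a non-negative scalar.
#' @export
attn_distance <- function(position, stimulus, attention, r_exponent = 1) {
  if (length(position) != length(stimulus) ||
      length(position) != length(attention)) {
    stop("`position`, `stimulus` and `attention` must have equal length")
  }
  if (!(r_exponent > 0)) stop("`r_exponent` must be positive")
  d <- abs(position - stimulus)
  if (r_exponent == 1) sum(attention * d)
  else sum(attention * d^r_exponent)^(1 / r_exponent)
}

# Vectorised distances: one row per unit. `positions` is m x n.
attn_distance_mat <- function(positions, stimulus, attention, r_exponent = 1) {
  d <- abs(positions - rep(stimulus, each = nrow(positions)))
  if (r_exponent == 1) {
    as.vector(d %*% attention)
  } else {
    as.vector(d^r_exponent %*% attention)^(1 / r_exponent)
  }
}

#' Exponential receptive-field activation
#'
#' `act = zeta * exp(-zeta * distance)`: strictly decreasing in distance with
#' maximum `zeta` at the stimulus. `zeta` sets the steepness (broad anterior
#' vs narrow posterior tuning in the dual-bank model).
#'
#' @param distance non-negative distance(s).
#' @param zeta positive tuning steepness.
#' @return activation value(s), vectorised over `distance`.
#' @export
unit_activation <- function(distance, zeta) {
  if (!(zeta > 0)) stop("`zeta` must be positive")
  if (any(distance < 0)) stop("`distance` must be non-negative")
  zeta * exp(-zeta * distance)
}

#' k-winners-take-all selection
#'
#' Returns the indices of the `K = max(1, round(k_prop * n_units))` eligible
#' units with the largest activations. If fewer than `K` eligible units
#' exist, all of them are returned; with no eligible units (e.g. the first
#' trial) the empty set is returned.
#'
#' Activations equal within a relative tolerance band are treated as tied;
#' ties are broken deterministically by recruitment-event id (newest first,
#' so freshly recruited units placed exactly at the stimulus win their
#' trigger trial) and then by lowest unit index. This keeps winner selection
#' identical across population sizes, which underwrites the model's
#' scale-invariance property.
#'
#' @param activations numeric vector of activations (full population length;
#'   values of ineligible units are ignored).
#' @param eligible logical mask of units allowed to win.
#' @param k_prop winner proportion.
#' @param n_units population size used to compute `K`.
#' @param batch optional integer recruitment-event id per unit used for
#'   tie-breaking.
#' @param tol relative tolerance for treating activations as tied.
#' @return sorted integer vector of winner indices (possibly empty).
#' @export
select_winners <- function(activations, eligible, k_prop, n_units,
                           batch = NULL, tol = 1e-9) {
  idx <- which(eligible)
  if (length(idx) == 0L) return(integer(0))
  K <- max(1L, as.integer(round(k_prop * n_units)))
  if (length(idx) <= K) return(idx)
  act <- activations[idx]
  ord <- order(act, decreasing = TRUE)
  aK <- act[ord[K]]
  eps <- tol * max(abs(act), 1e-300)
  definite <- act > aK + eps
  n_def <- sum(definite)
  if (n_def >= K) {
    # more "definite" than K can only happen through the band; fall back to
    # plain top-K in activation order (deterministic via order())
    return(sort(idx[ord[seq_len(K)]]))
  }
  tied <- which(!definite & act >= aK - eps)
  if (is.null(batch)) {
    key <- order(idx[tied])
  } else {
    b <- batch[idx[tied]]
    key <- order(-b, idx[tied])
  }
  take <- tied[key][seq_len(K - n_def)]
  sort(idx[c(which(definite), take)])
}

#' Winner outputs
#'
#' Only winners have non-zero output: `out_i = act_i` for winners, 0 for all
#' other units.
#'
#' @param activations numeric vector over the whole population.
#' @param winners integer indices of the winning units.
#' @return numeric vector of outputs, zero off the winner set.
#' @export
unit_outputs <- function(activations, winners) {
  out <- numeric(length(activations))
  if (length(winners)) out[winners] <- activations[winners]
  out
}

#' Category evidence from unit outputs
#'
#' `evidence_j = sum_i w_ij * out_i`: winner activations propagate to the
#' decision layer through the connection weights.
#'
#' @param outputs length-m output vector.
#' @param weights m x z connection-weight matrix.
#' @return length-z evidence vector.
#' @export
decision_evidence <- function(outputs, weights) {
  if (length(outputs) != nrow(weights)) {
    stop("`outputs` length must equal nrow(weights)")
  }
  as.vector(crossprod(weights, outputs))
}

# Fast path: evidence from winner rows only.
evidence_from_winners <- function(weights, activations, winners) {
  if (length(winners) == 0L) return(numeric(ncol(weights)))
  colSums(weights[winners, , drop = FALSE] * activations[winners])
}

#' Softmax choice probabilities
#'
#' `prob_j = exp(phi * evidence_j) / sum_v exp(phi * evidence_v)`, computed
#' with the usual max-shift so that extreme `phi * evidence` cannot overflow.
#' With `phi = 0` or zero evidence the distribution is uniform.
#'
#' @param evidence length-z evidence vector.
#' @param phi non-negative decision certainty (inverse temperature).
#' @return probability vector summing to 1.
#' @export
choice_probabilities <- function(evidence, phi) {
  if (phi < 0) stop("`phi` must be non-negative")
  e <- phi * evidence
  e <- e - max(e)
  x <- exp(e)
  x / sum(x)
}

#' Full forward pass of the population model
#'
#' Chains [attn_distance()] -> [unit_activation()] -> [select_winners()] ->
#' [unit_outputs()] -> [decision_evidence()] -> [choice_probabilities()].
#' Distances and activations are computed only for eligible (connected,
#' non-lesioned) units; ineligible units are reported as `NA` and can never
#' win or contribute evidence.
#'
#' @param model a `sustain_model`.
#' @param stimulus stimulus location (length `n_features`).
#' @return an object of class `sustain_forward`: list with `distances`,
#'   `activations` (NA for ineligible units), `winners`, `outputs`,
#'   `evidence`, `probs`.
#' @export
forward_pass <- function(model, stimulus) {
  p <- model$params
  if (length(stimulus) != p$n_features) {
    stop("`stimulus` must have length n_features")
  }
  m <- p$n_units
  elig <- eligible_units(model)
  idx <- which(elig)
  distances <- rep(NA_real_, m)
  activations <- rep(NA_real_, m)
  if (length(idx)) {
    d <- attn_distance_mat(model$positions[idx, , drop = FALSE],
                           stimulus, model$attention, p$r_exponent)
    distances[idx] <- d
    activations[idx] <- unit_activation(d, p$zeta)
  }
  winners <- select_winners(activations, elig, p$k_prop, m, model$batch)
  outputs <- unit_outputs(ifelse(is.na(activations), 0, activations), winners)
  evidence <- evidence_from_winners(model$weights, outputs, winners)
  probs <- choice_probabilities(evidence, p$phi)
  structure(list(distances = distances, activations = activations,
                 winners = winners, outputs = outputs,
                 evidence = evidence, probs = probs),
            class = "sustain_forward")
}
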