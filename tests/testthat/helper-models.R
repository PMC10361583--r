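# Shared builders for small test models.

tiny_params <- function(n_units = 20L, k_prop = 0.1, n_features = 3L,
                        zeta = 2, phi = 2, eta_pos = 0.05, eta_group = 1,
                        eta_attn = 0.02, eta_cweights = 0.01) {
  sustain_params(zeta = zeta, phi = phi, eta_pos = eta_pos,
                 eta_group = eta_group, eta_attn = eta_attn,
                 eta_cweights = eta_cweights, k_prop = k_prop,
                 n_units = n_units, n_features = n_features)
}

# A model with `n_connected` units placed at given positions (rows recycled),
# remaining units unconnected.
manual_model <- function(params, positions, weights = NULL,
                         attention = NULL, batch = NULL) {
  model <- new_population(params, seed = 1L)
  k <- nrow(positions)
  model$positions[seq_len(k), ] <- positions
  model$connected[seq_len(k)] <- TRUE
  model$batch[seq_len(k)] <- if (is.null(batch)) 1L else batch
  model$n_events <- max(model$batch)
  if (!is.null(weights)) model$weights[seq_len(k), ] <- weights
  if (!is.null(attention)) model$attention <- attention
  model
}

# Random simplex vector.
rand_simplex <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}
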