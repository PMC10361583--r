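#' Create a fresh population of neuron-like units
#'
#' Units are placed uniformly at random in the unit hypercube `[0,1]^n`
#' (the stimulus feature space). All units start unconnected: they do not
#' activate, win, or output until recruited. Connection weights of
#' never-connected units are exactly zero. Attention starts uniform over
#' feature dimensions.
#'
#' @param params a [sustain_params()] object.
#' @param seed optional integer seed for the unit placement; when supplied the
#'   R random stream is seeded before drawing positions.
#' @param connected logical; if `TRUE` all units start connected (used by the
#'   unsupervised spatial simulations, which assume the whole population is
#'   relevant to the current context).
#' @return an object of class `sustain_model`: a list with elements
#'   `params`, `positions` (m x n), `connected`, `lesioned`, `batch`
#'   (recruitment-event id per unit, 0 = never recruited), `weights` (m x z),
#'   `attention` (length n, non-negative, sums to 1), `n_events`, `trial`.
#' @export
new_population <- function(params, seed = NULL, connected = FALSE) {
  stopifnot(inherits(params, "sustain_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- params$n_units
  n <- params$n_features
  z <- params$n_decisions
  model <- list(
    params = params,
    positions = matrix(stats::runif(m * n), nrow = m, ncol = n),
    connected = rep(connected, m),
    lesioned = rep(FALSE, m),
    batch = rep(if (connected) 1L else 0L, m),
    weights = matrix(0, nrow = m, ncol = z),
    attention = rep(1 / n, n),
    n_events = if (connected) 1L else 0L,
    trial = 0L
  )
  class(model) <- "sustain_model"
  model
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("SUSTAIN-d model state\n")
  cat(sprintf("  %d units (%d connected, %d lesioned), %d features, %d decisions\n",
              x$params$n_units, sum(x$connected), sum(x$lesioned),
              x$params$n_features, x$params$n_decisions))
  cat(sprintf("  trials seen: %d   recruitment events: %d\n",
              x$trial, x$n_events))
  cat("  attention:", paste(sprintf("%.3f", x$attention), collapse = " "), "\n")
  invisible(x)
}

# Units allowed to activate, win, output and update.
eligible_units <- function(model) model$connected & !model$lesioned

#' Save / load a model state archive
#'
#' Round-trips the full model state (positions, masks, weights, attention,
#' parameters, counters) bit-exactly through R's native serialization.
#'
#' @param model a `sustain_model` (or any result list containing one).
#' @param path file path for the archive.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   restored object.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
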