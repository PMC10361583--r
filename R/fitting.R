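#' Model learning curves for a parameter set
#'
#' Trains the model on each requested problem over the shared seeded
#' sequences and returns the per-block error curves as a `n_blocks x
#' length(problems)` matrix.
#'
#' @param params a [sustain_params()] object.
#' @param seeds integer vector of run seeds (shared across parameter sets
#'   during fitting).
#' @param problems integer vector of Shepard types.
#' @param n_blocks number of 16-trial blocks.
#' @return matrix of block errors, one column per problem.
#' @export
model_curves <- function(params, seeds, problems = 1:6, n_blocks = 16L) {
  vapply(problems, function(pt) {
    recs <- train_on_problem(params, shepard_structure(pt), n_blocks, seeds)
    error_curve(recs, n_keep = n_blocks)
  }, numeric(n_blocks))
}

# Sum of squared errors between model and reference curves (all problems).
curves_sse <- function(model, reference) {
  sum((model - reference)^2)
}

expand_grid_list <- function(grid_spec) {
  g <- expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

refine_grid <- function(grid_spec, best, bounds) {
  out <- list()
  for (nm in names(grid_spec)) {
    vals <- sort(unique(grid_spec[[nm]]))
    b <- best[[nm]]
    if (length(vals) < 2L) {
      out[[nm]] <- b
      next
    }
    step <- min(diff(vals)) / 2
    cand <- unique(c(b - step, b, b + step))
    lim <- bounds[[nm]]
    if (!is.null(lim)) cand <- cand[cand >= lim[1] & cand <= lim[2]]
    out[[nm]] <- cand
  }
  out
}

param_bounds <- list(zeta = c(1e-6, Inf), phi = c(0, Inf),
                     eta_pos = c(0, 1), eta_group = c(0, 1),
                     eta_attn = c(0, Inf), eta_cweights = c(0, Inf))

#' Hierarchical grid-search fit to reference learning curves
#'
#' Two-stage coarse-to-fine grid search over the six free parameters
#' (`zeta`, `phi`, and the four learning rates). The objective is the summed
#' SSE between the model's and the reference's per-block error curves across
#' all problems, computed with the same fixed seeds for every parameter set.
#' The second stage re-searches a halved-spacing grid around the stage-one
#' incumbent.
#'
#' @param reference_curves `n_blocks x length(problems)` matrix of reference
#'   block errors (e.g. from [reference_curves()]).
#' @param grid_spec named list of candidate values per free parameter;
#'   parameters omitted keep their value from `base_params`.
#' @param seeds integer vector of run seeds shared by every evaluation.
#' @param base_params template [sustain_params()].
#' @param problems integer vector of Shepard types matching the reference
#'   columns.
#' @param refine logical; run the second (refinement) stage.
#' @return a `fit_result`: list with `best_params`, `sse`, and
#'   `grid_evaluations` (data.frame of every evaluated point and its SSE).
#' @export
fit_parameters <- function(reference_curves, grid_spec, seeds,
                           base_params = default_shepard_params(),
                           problems = 1:6, refine = TRUE) {
  if (length(grid_spec) == 0L || any(lengths(grid_spec) == 0L)) {
    stop("`grid_spec` must provide at least one value per parameter")
  }
  n_blocks <- nrow(reference_curves)
  evaluate <- function(points) {
    vapply(points, function(pt) {
      params <- base_params
      params[names(pt)] <- pt
      curves_sse(model_curves(params, seeds, problems, n_blocks),
                 reference_curves)
    }, numeric(1))
  }
  points <- expand_grid_list(grid_spec)
  sse <- evaluate(points)
  evals <- cbind(do.call(rbind.data.frame, points), sse = sse,
                 stage = 1L)
  best_i <- which.min(sse)
  best <- points[[best_i]]
  best_sse <- sse[best_i]
  if (refine) {
    grid2 <- refine_grid(grid_spec, best, param_bounds)
    points2 <- expand_grid_list(grid2)
    sse2 <- evaluate(points2)
    evals <- rbind(evals, cbind(do.call(rbind.data.frame, points2),
                                sse = sse2, stage = 2L))
    if (min(sse2) < best_sse) {
      best <- points2[[which.min(sse2)]]
      best_sse <- min(sse2)
    }
  }
  best_params <- base_params
  best_params[names(best)] <- best
  structure(list(best_params = best_params, sse = best_sse,
                 grid_evaluations = evals),
            class = "fit_result")
}

#' Grid-search fit of the dual-bank model
#'
#' Same protocol as [fit_parameters()] but over per-bank parameters. Grid
#' names are prefixed `anterior_` or `posterior_` (e.g. `anterior_zeta`);
#' combinations violating the tuning-breadth constraint
#' `anterior_zeta < posterior_zeta` are rejected before evaluation.
#'
#' @param reference_curves `n_blocks x length(problems)` reference matrix.
#' @param grid_spec named list with `anterior_`/`posterior_` prefixed names.
#' @param seeds shared run seeds.
#' @param base_params template [dual_params()].
#' @param problems Shepard types matching the reference columns.
#' @param refine logical; run the refinement stage.
#' @return a `fit_result` whose `best_params` is a [dual_params()].
#' @export
fit_dual_parameters <- function(reference_curves, grid_spec, seeds,
                                base_params, problems = 1:6,
                                refine = TRUE) {
  stopifnot(inherits(base_params, "dual_params"))
  n_blocks <- nrow(reference_curves)
  apply_point <- function(pt) {
    ant <- base_params$anterior
    post <- base_params$posterior
    for (nm in names(pt)) {
      if (startsWith(nm, "anterior_")) {
        ant[[sub("^anterior_", "", nm)]] <- pt[[nm]]
      } else if (startsWith(nm, "posterior_")) {
        post[[sub("^posterior_", "", nm)]] <- pt[[nm]]
      } else stop("grid names must be prefixed anterior_/posterior_")
    }
    if (!(ant$zeta < post$zeta)) return(NULL)
    dual_params(ant, post)
  }
  evaluate <- function(points) {
    vapply(points, function(pt) {
      dp <- apply_point(pt)
      if (is.null(dp)) return(NA_real_)
      model <- vapply(problems, function(ptype) {
        recs <- dual_train(dp, shepard_structure(ptype), n_blocks, seeds)
        error_curve(recs, n_keep = n_blocks)
      }, numeric(n_blocks))
      curves_sse(model, reference_curves)
    }, numeric(1))
  }
  points <- expand_grid_list(grid_spec)
  sse <- evaluate(points)
  if (all(is.na(sse))) stop("no grid point satisfies anterior_zeta < posterior_zeta")
  evals <- cbind(do.call(rbind.data.frame, points), sse = sse, stage = 1L)
  best_i <- which.min(sse)
  best <- points[[best_i]]
  best_sse <- sse[best_i]
  if (refine) {
    grid2 <- refine_grid(grid_spec, best, NULL)
    points2 <- expand_grid_list(grid2)
    sse2 <- evaluate(points2)
    evals <- rbind(evals, cbind(do.call(rbind.data.frame, points2),
                                sse = sse2, stage = 2L))
    if (min(sse2, na.rm = TRUE) < best_sse) {
      best <- points2[[which.min(sse2)]]
      best_sse <- min(sse2, na.rm = TRUE)
    }
  }
  structure(list(best_params = apply_point(best), sse = best_sse,
                 grid_evaluations = evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("grid-search fit: %d evaluations, best SSE = %.6g\n",
              nrow(x$grid_evaluations), x$sse))
  invisible(x)
}
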