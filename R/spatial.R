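#' Random foraging trajectory in the unit square
#'
#' Simulates an agent moving left, right, up, or down in steps of 0, 0.025,
#' 0.05, or 0.075 (direction and step size uniform), with the restriction
#' that it cannot step out of the `[0,1]^2` environment: out-of-bounds
#' proposals are resampled until valid. Deterministic given `seed`.
#'
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param start starting position (default centre).
#' @return list with `points` (n_steps x 2 matrix of visited positions,
#'   after each step) and `seed`.
#' @export
generate_trajectory <- function(n_steps, seed, start = c(0.5, 0.5)) {
  stopifnot(n_steps >= 1)
  set.seed(as.integer(seed))
  dirs <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2, byrow = TRUE)
  sizes <- c(0, 0.025, 0.05, 0.075)
  pts <- matrix(NA_real_, nrow = n_steps, ncol = 2)
  pos <- start
  for (t in seq_len(n_steps)) {
    repeat {
      step <- dirs[sample.int(4L, 1L), ] * sizes[sample.int(4L, 1L)]
      cand <- pos + step
      if (cand[1] >= 0 && cand[1] <= 1 && cand[2] >= 0 && cand[2] <= 1) {
        pos <- cand
        break
      }
    }
    pts[t, ] <- pos
  }
  list(points = pts, seed = as.integer(seed))
}

#' Annealing schedule for the spatial Kohonen rate
#'
#' `eta_t = eta0 / (1 + rho * t)`: non-increasing in `t`, recovering `eta0`
#' at `t = 0`. The default annealing rate `rho = 4e-12` is negligible over
#' typical run lengths but lets unit positions settle in very long runs.
#'
#' @param eta0 initial learning rate.
#' @param rho annealing rate.
#' @return an `anneal_schedule` list with an `eta_at(t)` accessor.
#' @export
anneal_schedule <- function(eta0 = 0.25, rho = 4e-12) {
  stopifnot(eta0 >= 0, rho >= 0)
  structure(list(eta0 = eta0, rho = rho,
                 eta_at = function(t) eta0 / (1 + rho * t)),
            class = "anneal_schedule")
}

#' Unsupervised spatial learning on a foraging trajectory
#'
#' All units are connected from the start (the whole population is assumed
#' relevant to the spatial context); there is no recruitment, no attention
#' learning (attention is fixed uniform over the two spatial dimensions) and
#' no category output. At each step the `K` most activated units win, take a
#' Kohonen step toward the agent's position with the annealed rate, and then
#' contract toward their centroid with rate `eta_group` (1.0 by default,
#' which welds each winning set into a co-located flock).
#'
#' @param params a [sustain_params()] with `n_features = 2`.
#' @param trajectory result of [generate_trajectory()].
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed for the initial uniform unit placement.
#' @return the trained `sustain_model` with frozen positions.
#' @export
train_spatial <- function(params, trajectory,
                          schedule = anneal_schedule(), seed = 1L) {
  stopifnot(params$n_features == 2L)
  model <- new_population(params, seed = seed, connected = TRUE)
  K <- n_winners(params)
  m <- params$n_units
  pos <- model$positions
  a <- model$attention
  eta0 <- schedule$eta0
  rho <- schedule$rho
  eg <- params$eta_group
  pts <- trajectory$points
  for (t in seq_len(nrow(pts))) {
    x <- pts[t, ]
    d <- a[1] * abs(pos[, 1] - x[1]) + a[2] * abs(pos[, 2] - x[2])
    if (K < m) {
      thr <- sort(d, partial = K)[K]
      w <- which(d <= thr)
      if (length(w) > K) w <- w[order(d[w], w)][seq_len(K)]
    } else {
      w <- seq_len(m)
    }
    eta_t <- eta0 / (1 + rho * t)
    P <- pos[w, , drop = FALSE]
    P <- P + eta_t * (rep(x, each = length(w)) - P)
    if (eg > 0 && length(w) > 1L) {
      ctr <- colMeans(P)
      P <- P + eg * (rep(ctr, each = length(w)) - P)
    }
    pos[w, ] <- P
  }
  model$positions <- pos
  model$trial <- nrow(pts)
  model
}

#' Occupancy-normalised activation map
#'
#' Freezes the trained unit positions, replays a fresh test trajectory, and
#' at each visited position accumulates the summed activation of the `K`
#' winning units into a `bins x bins` spatial grid. Each bin's accumulated
#' activation is divided by its visit count; bins never visited are `NA`
#' (missing), not zero.
#'
#' @param model a trained `sustain_model` (2-D).
#' @param test_trajectory result of [generate_trajectory()].
#' @param bins grid resolution per side (default 40).
#' @return an `activation_map`: list with `values` (bins x bins, NA where
#'   unvisited), `visits` (counts) and `bins`.
#' @export
activation_map <- function(model, test_trajectory, bins = 40L) {
  p <- model$params
  stopifnot(p$n_features == 2L)
  idx <- which(eligible_units(model))
  pos <- model$positions[idx, , drop = FALSE]
  K <- min(n_winners(p), nrow(pos))
  a <- model$attention
  zeta <- p$zeta
  pts <- test_trajectory$points
  acc <- matrix(0, bins, bins)
  visits <- matrix(0L, bins, bins)
  bin_of <- function(v) pmin(bins, pmax(1L, as.integer(ceiling(v * bins))))
  bx <- bin_of(pts[, 1])
  by <- bin_of(pts[, 2])
  for (t in seq_len(nrow(pts))) {
    x <- pts[t, ]
    d <- a[1] * abs(pos[, 1] - x[1]) + a[2] * abs(pos[, 2] - x[2])
    if (K < length(d)) {
      thr <- sort(d, partial = K)[K]
      w <- which(d <= thr)
      if (length(w) > K) w <- w[order(d[w], w)][seq_len(K)]
    } else {
      w <- seq_along(d)
    }
    s <- sum(zeta * exp(-zeta * d[w]))
    acc[bx[t], by[t]] <- acc[bx[t], by[t]] + s
    visits[bx[t], by[t]] <- visits[bx[t], by[t]] + 1L
  }
  values <- acc / visits
  values[visits == 0L] <- NA_real_
  structure(list(values = values, visits = visits, bins = as.integer(bins)),
            class = "activation_map")
}

#' Flock centroids and tiling regularity
#'
#' Clusters final unit positions by single linkage at threshold `eps`,
#' returns the cluster centroids, and summarises tiling regularity as the
#' coefficient of variation (CV) of nearest-neighbour distances among
#' centroids. A regular (grid-like) tiling has a lower CV than matched
#' uniform-random points; the Monte-Carlo control CV for the same number of
#' points is returned alongside.
#'
#' Because the recurrent update collapses every winning set onto its
#' centroid, trained units end up exactly co-located in assemblies; the
#' `assembly_frac` diagnostic (fraction of units lying in a co-located
#' cluster of at least `min_assembly` units) separates flocking from plain
#' competitive learning, which leaves units dispersed.
#'
#' @param model a trained 2-D `sustain_model`.
#' @param eps single-linkage threshold (Euclidean, default 0.05).
#' @param n_control Monte-Carlo draws for the uniform-random control.
#' @param control_seed seed for the control draws.
#' @param co_eps co-location threshold for assembly membership.
#' @param min_assembly minimum co-located cluster size counted as an
#'   assembly.
#' @return list with `centroids`, `n_flocks`, `assembly_frac`, `nn_cv`,
#'   `control_cv` (median CV of matched uniform-random point sets; `nn_cv`
#'   is NA when fewer than 5 centroids exist, in which case the tiling
#'   diagnostic fails).
#' @export
flock_tiling <- function(model, eps = 0.05, n_control = 200L,
                         control_seed = 1L, co_eps = 1e-6,
                         min_assembly = 3L) {
  idx <- which(eligible_units(model))
  pos <- model$positions[idx, , drop = FALSE]
  co <- stats::cutree(stats::hclust(stats::dist(pos), method = "single"),
                      h = co_eps)
  sizes <- table(co)
  assembly_frac <- sum(sizes[sizes >= min_assembly]) / nrow(pos)
  uni <- unique(round(pos, 9))
  if (nrow(uni) > 1L) {
    hc <- stats::hclust(stats::dist(uni), method = "single")
    cl <- stats::cutree(hc, h = eps)
  } else {
    cl <- rep(1L, nrow(uni))
  }
  cent <- do.call(rbind, lapply(split(seq_len(nrow(uni)), cl), function(i) {
    colMeans(uni[i, , drop = FALSE])
  }))
  n_flocks <- nrow(cent)
  nn_cv_of <- function(xy) {
    dm <- as.matrix(stats::dist(xy))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, min)
    stats::sd(nn) / mean(nn)
  }
  if (n_flocks < 5L) {
    return(list(centroids = cent, n_flocks = n_flocks,
                assembly_frac = assembly_frac,
                nn_cv = NA_real_, control_cv = NA_real_))
  }
  nn_cv <- nn_cv_of(cent)
  set.seed(as.integer(control_seed))
  ctrl <- vapply(seq_len(n_control), function(i) {
    nn_cv_of(matrix(stats::runif(2 * n_flocks), ncol = 2))
  }, numeric(1))
  list(centroids = cent, n_flocks = n_flocks,
       assembly_frac = assembly_frac,
       nn_cv = nn_cv, control_cv = stats::median(ctrl))
}

#' Foraging experiment: grid scores over repeated simulations
#'
#' Repeats trajectory generation, spatial training, activation mapping and
#' grid scoring with independent seeds, and collects the score distribution
#' together with the tiling diagnostics.
#'
#' @param params a [sustain_params()] with `n_features = 2`.
#' @param n_sims number of simulations.
#' @param n_steps learning-trajectory length.
#' @param test_steps test-trajectory length for the activation map.
#' @param schedule an [anneal_schedule()].
#' @param seed base integer seed; simulation `i` derives its seeds from it.
#' @param keep_maps logical; retain each simulation's map and
#'   autocorrelogram.
#' @return list with `results` (data.frame: sim, grid_score, n_flocks,
#'   nn_cv, control_cv) and optionally `maps`.
#' @export
spatial_experiment <- function(params, n_sims = 10L, n_steps = 50000L,
                               test_steps = 25000L,
                               schedule = anneal_schedule(), seed = 1L,
                               keep_maps = FALSE) {
  seed <- as.integer(seed) %% 2100000000L
  rows <- vector("list", n_sims)
  maps <- if (keep_maps) vector("list", n_sims) else NULL
  for (i in seq_len(n_sims)) {
    s <- (seed + 7919L * i) %% 2100000000L
    traj <- generate_trajectory(n_steps, seed = s)
    model <- train_spatial(params, traj, schedule, seed = s + 1L)
    test <- generate_trajectory(test_steps, seed = s + 2L)
    amap <- activation_map(model, test)
    sac <- spatial_autocorrelogram(amap)
    gs <- grid_score(sac)
    til <- flock_tiling(model)
    rows[[i]] <- data.frame(sim = i, grid_score = gs$grid_score,
                            n_flocks = til$n_flocks,
                            assembly_frac = til$assembly_frac,
                            nn_cv = til$nn_cv, control_cv = til$control_cv)
    if (keep_maps) maps[[i]] <- list(map = amap, sac = sac, score = gs)
  }
  out <- list(results = do.call(rbind, rows))
  if (keep_maps) out$maps <- maps
  out
}
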