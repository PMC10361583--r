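#' The six Shepard-Hovland-Jenkins category structures
#'
#' Eight stimuli formed by all combinations of three binary features, split
#' 4 vs 4 into two categories. Type I is solvable from one feature; type II
#' is exclusive-or on two features; types III-V are rule-plus-exception
#' variants; type VI is three-feature parity, where no feature subset
#' predicts the category. Human learning difficulty orders
#' I < II <= III, IV, V < VI.
#'
#' @param problem_type integer 1-6 or roman numeral string ("I".."VI").
#' @return an object of class `shepard_structure`: list with `problem_type`,
#'   `stimuli` (8 x 3 binary matrix) and `labels` (length-8 integer vector of
#'   category labels 1/2).
#' @examples
#' s <- shepard_structure("VI")
#' table(s$labels)
#' @export
shepard_structure <- function(problem_type) {
  roman <- c("I", "II", "III", "IV", "V", "VI")
  if (is.character(problem_type)) {
    problem_type <- match(toupper(problem_type), roman)
  }
  problem_type <- as.integer(problem_type)
  if (is.na(problem_type) || problem_type < 1L || problem_type > 6L) {
    stop("`problem_type` must be I-VI (1-6)")
  }
  stimuli <- as.matrix(expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1))
  dimnames(stimuli) <- list(NULL, c("f1", "f2", "f3"))
  key <- stimuli %*% c(4, 2, 1)  # f1 f2 f3 as binary digits
  # category-A member sets (canonical assignments, one representative of
  # each of the six equivalence classes of 4-subsets of the 3-cube)
  a_sets <- list(
    c(0, 1, 2, 3),   # I:   f1 = 0
    c(0, 1, 6, 7),   # II:  f1 == f2 (XOR complement)
    c(0, 1, 2, 5),   # III: rule plus exception
    c(0, 1, 2, 4),   # IV:  within Hamming distance 1 of 000
    c(0, 1, 2, 7),   # V:   f1 = 0 with the 011 <-> 111 pair swapped
    c(0, 3, 5, 6)    # VI:  even parity
  )
  labels <- ifelse(key %in% a_sets[[problem_type]], 1L, 2L)
  structure(list(problem_type = problem_type,
                 stimuli = stimuli, labels = as.integer(labels)),
            class = "shepard_structure")
}

#' Randomised trial sequence in blocks of 16
#'
#' Concatenates `n_blocks` independently shuffled blocks, each containing
#' two repetitions of each of the 8 stimuli in randomised order (16 trials
#' per block). Deterministic given `seed`, so the same sequences can be
#' reused across parameter sets during fitting.
#'
#' @param structure a [shepard_structure()].
#' @param n_blocks number of 16-trial blocks.
#' @param seed integer seed.
#' @return list with `stimuli` (16*n_blocks x 3 matrix), `labels`, `n_blocks`,
#'   `block_size = 16`, `seed`.
#' @export
make_trial_sequence <- function(structure, n_blocks, seed) {
  stopifnot(inherits(structure, "shepard_structure"), n_blocks >= 1)
  set.seed(as.integer(seed))
  order_idx <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(seq_len(8L), 2L))
  }))
  list(stimuli = structure$stimuli[order_idx, , drop = FALSE],
       labels = structure$labels[order_idx],
       n_blocks = as.integer(n_blocks), block_size = 16L,
       seed = as.integer(seed))
}

#' Train the model on one Shepard problem
#'
#' Runs supervised trial-and-error learning over one or more seeded trial
#' sequences. For each seed, the trial sequence, the unit placement and the
#' training noise stream are all derived deterministically from that seed,
#' so runs are exactly reproducible and the same sequences are shared across
#' parameter sets.
#'
#' @param params a [sustain_params()] object.
#' @param structure a [shepard_structure()].
#' @param n_blocks number of 16-trial blocks.
#' @param seeds integer vector of run seeds (one training run per seed).
#' @param noise_sd per-winner Gaussian update-noise SD (0 for none).
#' @param noise_mode noise injection mode, see [training_step()].
#' @param lesion optional [lesion_spec()]; applied at the start of the given
#'   trial.
#' @return a list of run records, each a list with `prob_correct` (per-trial
#'   correct-category probability), `n_events` (recruitment events),
#'   `model` (final state), `seed`.
#' @export
train_on_problem <- function(params, structure, n_blocks, seeds,
                             noise_sd = 0, noise_mode = "update",
                             lesion = NULL) {
  lapply(seeds, function(seed) {
    seed <- as.integer(seed) %% 2147480000L
    seq <- make_trial_sequence(structure, n_blocks, seed)
    model <- new_population(params, seed = (seed + 500003L) %% 2147480000L)
    set.seed((seed + 1000033L) %% 2147480000L)  # noise + lesion stream
    n_trials <- nrow(seq$stimuli)
    probs <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      if (!is.null(lesion) && t == lesion$trial) {
        model <- apply_lesion(model, lesion)
      }
      step <- training_step(model, seq$stimuli[t, ], seq$labels[t],
                            noise_sd = noise_sd, noise_mode = noise_mode)
      model <- step$model
      probs[t] <- step$prob_correct
    }
    list(prob_correct = probs, n_events = model$n_events,
         model = model, seed = seed)
  })
}

#' Block error curve from training records
#'
#' Averages, over runs, the per-block mean of `1 - prob_correct`. Only the
#' first `n_keep` blocks are retained (16 by default, matching the span used
#' for fitting behavioural curves).
#'
#' @param records result of [train_on_problem()].
#' @param block_size trials per block (16).
#' @param n_keep number of leading blocks to keep (`Inf` for all).
#' @return numeric vector of per-block error, one entry per block.
#' @export
error_curve <- function(records, block_size = 16L, n_keep = 16L) {
  nk <- min(n_keep, length(records[[1]]$prob_correct) %/% block_size)
  per_run <- vapply(records, function(rec) {
    err <- 1 - rec$prob_correct
    n_blocks <- length(err) %/% block_size
    blocks <- colMeans(matrix(err[seq_len(n_blocks * block_size)],
                              nrow = block_size))
    blocks[seq_len(nk)]
  }, numeric(nk))
  rowMeans(matrix(per_run, nrow = nk))
}

#' Count virtual clusters (flocks)
#'
#' A flock is a group of units with near-identical tuning. Flocks are
#' identified as connected components of the active units under
#' single-linkage clustering with the model's attention-weighted distance
#' and threshold `eps` (default 0.1 in the unit cube). In noiseless training
#' every recruitment batch is exactly co-located, so the count can be
#' cross-checked against the number of distinct recruitment sites; attention
#' weights that collapse to zero merge flocks that differ only on an ignored
#' feature, which is what yields the modal counts 2, 4, 6, 6, 6, 8 on
#' problems I-VI.
#'
#' @param model a trained `sustain_model`.
#' @param eps single-linkage distance threshold.
#' @return integer number of flocks (0 with no connected units).
#' @export
count_flocks <- function(model, eps = 0.1) {
  idx <- which(eligible_units(model))
  if (length(idx) == 0L) return(0L)
  pos <- model$positions[idx, , drop = FALSE]
  uni <- unique(round(pos, 9))
  if (nrow(uni) == 1L) return(1L)
  a <- model$attention
  r <- model$params$r_exponent
  n <- nrow(uni)
  dm <- matrix(0, n, n)
  for (j in seq_len(ncol(uni))) {
    dj <- abs(outer(uni[, j], uni[, j], "-"))
    dm <- dm + a[j] * (if (r == 1) dj else dj^r)
  }
  if (r != 1) dm <- dm^(1 / r)
  hc <- stats::hclust(stats::as.dist(dm), method = "single")
  max(stats::cutree(hc, h = eps))
}

#' Modal flock count over seeded runs
#'
#' @param records result of [train_on_problem()].
#' @param eps single-linkage threshold passed to [count_flocks()].
#' @return the most frequent flock count (ties broken toward the smaller).
#' @export
modal_flock_count <- function(records, eps = 0.1) {
  counts <- vapply(records, function(rec) count_flocks(rec$model, eps),
                   integer(1))
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])
}
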