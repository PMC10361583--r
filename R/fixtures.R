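#' Synthetic reference learning curves
#'
#' Generates the package's offline stand-in for behavioural learning curves:
#' the model's own block-error curves on the six Shepard problems under a
#' documented fixture parameter set, carrying the qualitative human
#' signature (difficulty ordering I < II <= III, IV, V < VI). The curves
#' regenerate bit-identically from the seeds, so the fitting machinery is
#' testable with no external data. These curves are synthetic, not human
#' data.
#'
#' @param params fixture parameter set (default [default_shepard_params()]).
#' @param seeds integer vector of run seeds.
#' @param n_blocks number of 16-trial blocks.
#' @return a `n_blocks x 6` matrix of block errors (columns = types I-VI).
#' @export
reference_curves <- function(params = default_shepard_params(),
                             seeds = 1:25, n_blocks = 16L) {
  curves <- model_curves(params, seeds, problems = 1:6, n_blocks = n_blocks)
  colnames(curves) <- c("I", "II", "III", "IV", "V", "VI")
  curves
}

#' Read / write learning curves as delimited text
#'
#' Tab-separated, one row per block, one column per problem, full double
#' precision (`%.17g`, which round-trips exactly).
#'
#' @param curves matrix of block errors.
#' @param path file path.
#' @return `write_curves` returns `path` invisibly; `read_curves` returns
#'   the curve matrix.
#' @export
write_curves <- function(curves, path) {
  df <- data.frame(block = seq_len(nrow(curves)),
                   apply(curves, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df[, -1, drop = FALSE])
}

#' Read / write a task structure as delimited text
#'
#' Eight rows of `f1 f2 f3 label`, tab-separated.
#'
#' @param structure a [shepard_structure()].
#' @param path file path.
#' @return `write_structure` returns `path` invisibly; `read_structure`
#'   returns a `shepard_structure`-compatible list (with `problem_type = NA`
#'   unless recoverable).
#' @export
write_structure <- function(structure, path) {
  df <- data.frame(structure$stimuli, label = structure$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- list(problem_type = NA_integer_,
              stimuli = as.matrix(df[, 1:3]),
              labels = as.integer(df$label))
  class(out) <- "shepard_structure"
  out
}

#' Read / write a trajectory as delimited text
#'
#' Tab-separated `t x y` rows.
#'
#' @param trajectory result of [generate_trajectory()].
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a trajectory list.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(t = seq_len(nrow(trajectory$points)),
                   x = sprintf("%.17g", trajectory$points[, 1]),
                   y = sprintf("%.17g", trajectory$points[, 2]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  list(points = cbind(df$x, df$y), seed = NA_integer_)
}
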