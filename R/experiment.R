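#' Run a named experiment from a configuration
#'
#' Executes one of the package's experiments from a validated configuration
#' (an R list or a YAML file path) and writes a run archive next to a copy
#' of the fully resolved configuration and a plain-text log. Identical
#' configurations produce identical archives.
#'
#' Recognised `experiment` values:
#' \describe{
#'   \item{`shepard`}{supervised learning on Shepard problems; fields
#'     `problems`, `n_blocks`, `seeds`, `params` (a named list overriding
#'     [default_shepard_params()]), optional `noise_sd`, `lesion`
#'     (`trial`, `n_remove`).}
#'   \item{`forage`}{unsupervised spatial learning; fields `n_sims`,
#'     `n_steps`, `test_steps`, `seed`, `params` overriding
#'     [default_spatial_params()].}
#'   \item{`robustness`}{full-factorial sweep; fields as in
#'     [robustness_sweep()].}
#'   \item{`dual`}{dual-bank learning; fields `problems`, `n_blocks`,
#'     `seeds`, optional `anterior`/`posterior` overrides of
#'     [default_dual_params()].}
#' }
#'
#' @param config list or path to a YAML configuration file.
#' @param out_dir directory for the archive (created if needed).
#' @param dry_run validate the configuration without executing.
#' @return invisibly, the path to the archive (`NULL` for a dry run).
#' @export
run_experiment <- function(config, out_dir = ".", dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$experiment) ||
      !config$experiment %in% c("shepard", "forage", "robustness", "dual")) {
    stop("config field `experiment` must be one of shepard/forage/robustness/dual")
  }
  override <- function(base, lst) {
    for (nm in names(lst)) base[[nm]] <- lst[[nm]]
    base
  }
  resolved <- config
  result <- NULL
  if (config$experiment == "shepard") {
    if (is.null(config$seeds)) stop("config field `seeds` is required")
    params <- override(default_shepard_params(), config$params)
    resolved$params <- unclass(params)
    if (!dry_run) {
      problems <- if (is.null(config$problems)) 1:6 else config$problems
      n_blocks <- if (is.null(config$n_blocks)) 16L else config$n_blocks
      lesion <- if (!is.null(config$lesion)) {
        lesion_spec(config$lesion$trial, config$lesion$n_remove)
      }
      noise_sd <- if (is.null(config$noise_sd)) 0 else config$noise_sd
      result <- lapply(problems, function(pt) {
        recs <- train_on_problem(params, shepard_structure(pt), n_blocks,
                                 config$seeds, noise_sd = noise_sd,
                                 lesion = lesion)
        list(problem = pt, records = recs,
             curve = error_curve(recs, n_keep = n_blocks),
             modal_flocks = modal_flock_count(recs))
      })
    }
  } else if (config$experiment == "forage") {
    if (is.null(config$seed)) stop("config field `seed` is required")
    params <- override(default_spatial_params(), config$params)
    resolved$params <- unclass(params)
    if (!dry_run) {
      result <- spatial_experiment(
        params,
        n_sims = if (is.null(config$n_sims)) 10L else config$n_sims,
        n_steps = if (is.null(config$n_steps)) 50000L else config$n_steps,
        test_steps = if (is.null(config$test_steps)) 25000L else config$test_steps,
        seed = config$seed, keep_maps = TRUE)
    }
  } else if (config$experiment == "robustness") {
    if (is.null(config$seeds)) stop("config field `seeds` is required")
    if (!dry_run) {
      result <- robustness_sweep(
        problem_types = if (is.null(config$problems)) 1L else config$problems,
        n_units_grid = if (is.null(config$n_units)) c(20L, 1000L) else config$n_units,
        eta_group_grid = if (is.null(config$eta_group)) 1 else config$eta_group,
        noise_sds = if (is.null(config$noise_sd)) 0 else config$noise_sd,
        lesion_ns = if (is.null(config$lesion_n)) 0L else config$lesion_n,
        seeds = config$seeds)
    }
  } else if (config$experiment == "dual") {
    if (is.null(config$seeds)) stop("config field `seeds` is required")
    dp <- default_dual_params()
    dp$anterior <- override(dp$anterior, config$anterior)
    dp$posterior <- override(dp$posterior, config$posterior)
    resolved$anterior <- unclass(dp$anterior)
    resolved$posterior <- unclass(dp$posterior)
    if (!dry_run) {
      problems <- if (is.null(config$problems)) c(1L, 6L) else config$problems
      n_blocks <- if (is.null(config$n_blocks)) 16L else config$n_blocks
      result <- lapply(problems, function(pt) {
        recs <- dual_train(dp, shepard_structure(pt), n_blocks, config$seeds)
        list(problem = pt, records = recs,
             curve = error_curve(recs, n_keep = n_blocks))
      })
    }
  }
  if (dry_run) {
    message("configuration valid (dry run; nothing executed)")
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  archive <- file.path(out_dir, paste0(config$experiment, "_run.rds"))
  saveRDS(list(config = resolved, result = result,
               experiment = config$experiment), archive)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  writeLines(c(sprintf("experiment: %s", config$experiment),
               sprintf("finished: %s", format(Sys.time())),
               sprintf("R version: %s", R.version.string)),
             file.path(out_dir, "run.log"))
  invisible(archive)
}

#' Plot an activation map or autocorrelogram
#'
#' @param x an `activation_map` or a matrix (e.g. an autocorrelogram).
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.activation_map <- function(x, main = "activation map", ...) {
  graphics::image(x$values, main = main, useRaster = TRUE,
                  xlab = "", ylab = "", axes = FALSE, ...)
}

#' Plot learning curves for the six Shepard problems
#'
#' @param curves `n_blocks x p` matrix of block errors.
#' @param main plot title.
#' @export
plot_learning_curves <- function(curves, main = "learning curves") {
  p <- ncol(curves)
  graphics::matplot(curves, type = "o", pch = 16, lty = 1,
                    col = grDevices::hcl.colors(p, "Dark 3"),
                    xlab = "block", ylab = "P(error)", main = main,
                    ylim = c(0, 0.55))
  graphics::legend("topright", legend = colnames(curves) %||% seq_len(p),
                   col = grDevices::hcl.colors(p, "Dark 3"),
                   lty = 1, pch = 16, bty = "n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regenerate figures from a run archive
#'
#' Writes PNG panels appropriate to the archived experiment: learning-curve
#' panels and flock scatter plots for `shepard` runs, activation map and
#' autocorrelogram pairs for `forage` runs, per-cell curves for
#' `robustness`, and combined/anterior/posterior curve panels for `dual`
#' runs.
#'
#' @param archive path to an archive written by [run_experiment()] (or the
#'   list it contains).
#' @param out_dir output directory for the figures.
#' @return character vector of files written, invisibly.
#' @export
make_figures <- function(archive, out_dir = ".") {
  run <- if (is.character(archive)) readRDS(archive) else archive
  if (is.null(run$experiment)) stop("not a run archive: missing `experiment`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  png_open <- function(name) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = 900, height = 700, res = 110)
    path
  }
  if (run$experiment == "shepard") {
    curves <- vapply(run$result, `[[`, numeric(length(run$result[[1]]$curve)),
                     "curve")
    colnames(curves) <- vapply(run$result, function(r) as.character(r$problem),
                               character(1))
    files <- c(files, png_open("learning_curves.png"))
    plot_learning_curves(curves)
    grDevices::dev.off()
    files <- c(files, png_open("flock_positions.png"))
    mod <- run$result[[1]]$records[[1]]$model
    pos <- mod$positions[eligible_units(mod), , drop = FALSE]
    graphics::plot(pos[, 1], pos[, 2], pch = 16,
                   xlab = "feature 1", ylab = "feature 2",
                   main = "final unit positions (problem 1)")
    grDevices::dev.off()
  } else if (run$experiment == "forage") {
    maps <- run$result$maps
    if (is.null(maps)) stop("forage archive has no stored maps")
    for (i in seq_along(maps)) {
      files <- c(files, png_open(sprintf("map_sac_%02d.png", i)))
      graphics::par(mfrow = c(1, 2))
      plot(maps[[i]]$map, main = sprintf("sim %d map", i))
      graphics::image(maps[[i]]$sac, main = sprintf("sac (grid score %.2f)",
                                                    maps[[i]]$score$grid_score),
                      useRaster = TRUE, axes = FALSE)
      grDevices::dev.off()
    }
  } else if (run$experiment == "robustness") {
    files <- c(files, png_open("robustness.png"))
    tab <- run$result
    agg <- stats::aggregate(error ~ block + n_units + noise_sd + lesion_n +
                              eta_group, data = tab, FUN = mean)
    cells <- unique(agg[, c("n_units", "noise_sd", "lesion_n", "eta_group")])
    graphics::plot(NULL, xlim = range(agg$block), ylim = c(0, 0.6),
                   xlab = "block", ylab = "P(error)", main = "robustness sweep")
    for (i in seq_len(nrow(cells))) {
      sub <- merge(agg, cells[i, , drop = FALSE])
      graphics::lines(sub$block, sub$error, col = i)
    }
    grDevices::dev.off()
  } else if (run$experiment == "dual") {
    for (r in run$result) {
      files <- c(files, png_open(sprintf("dual_type%d.png", r$problem)))
      graphics::par(mfrow = c(1, 3))
      nb <- length(r$curve)
      graphics::plot(seq_len(nb), r$curve, type = "o", pch = 16,
                     xlab = "block", ylab = "P(error)", ylim = c(0, 0.55),
                     main = sprintf("combined output (type %d)", r$problem))
      for (bank in c("anterior", "posterior")) {
        acc <- rowMeans(sapply(r$records, function(rec) {
          p <- rec$bank_prob_correct[bank, ]
          colMeans(matrix(1 - p, nrow = 16L))
        }))
        graphics::plot(seq_along(acc), acc, type = "o", pch = 16,
                       xlab = "block", ylab = "P(error)", ylim = c(0, 0.55),
                       main = bank)
      }
      grDevices::dev.off()
    }
  }
  invisible(files)
}
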