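#' Spatial autocorrelogram of an activation map
#'
#' For every 2-D lag, the Pearson correlation between the map and its
#' shifted copy over the mutually valid (visited) bins — the standard
#' rate-map autocorrelogram. Output is `(2B-1) x (2B-1)` with the zero lag
#' at the centre (value 1). Lags with fewer than `min_overlap` valid
#' overlapping bins, or zero variance in the overlap, are `NA`.
#'
#' @param map an [activation_map()] (or any list with a `values` matrix).
#' @param min_overlap minimum number of valid overlapping bins per lag.
#' @return a `(2B-1) x (2B-1)` matrix of correlations with `NA` for
#'   undefined lags.
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20L) {
  v <- map$values
  B <- nrow(v)
  S <- 2L * B - 1L
  sac <- matrix(NA_real_, S, S)
  if (all(is.na(v)) || stats::var(as.vector(v), na.rm = TRUE) == 0) {
    warning("activation map is constant or empty; autocorrelogram undefined")
    return(sac)
  }
  for (dx in -(B - 1L):(B - 1L)) {
    r1 <- max(1L, 1L + dx):min(B, B + dx)
    r2 <- r1 - dx
    for (dy in -(B - 1L):(B - 1L)) {
      c1 <- max(1L, 1L + dy):min(B, B + dy)
      c2 <- c1 - dy
      a <- v[r1, c1]
      b <- v[r2, c2]
      ok <- !is.na(a) & !is.na(b)
      n <- sum(ok)
      if (n < min_overlap) next
      av <- a[ok]; bv <- b[ok]
      sa <- stats::sd(av); sb <- stats::sd(bv)
      if (sa == 0 || sb == 0) next
      sac[B + dx, B + dy] <- stats::cor(av, bv)
    }
  }
  sac
}

# Bilinear sample of matrix `m` at fractional index coordinates (u, v).
# Returns NA outside the matrix or when any of the four neighbours is NA.
bilinear_sample <- function(m, u, v) {
  S <- nrow(m)
  out <- rep(NA_real_, length(u))
  i0 <- floor(u); j0 <- floor(v)
  ok <- i0 >= 1 & j0 >= 1 & i0 + 1 <= S & j0 + 1 <= S
  if (!any(ok)) return(out)
  i0k <- i0[ok]; j0k <- j0[ok]
  fu <- u[ok] - i0k; fv <- v[ok] - j0k
  m00 <- m[cbind(i0k, j0k)]
  m10 <- m[cbind(i0k + 1, j0k)]
  m01 <- m[cbind(i0k, j0k + 1)]
  m11 <- m[cbind(i0k + 1, j0k + 1)]
  val <- m00 * (1 - fu) * (1 - fv) + m10 * fu * (1 - fv) +
    m01 * (1 - fu) * fv + m11 * fu * fv
  out[ok] <- val
  out
}

#' Expanding-annulus grid score
#'
#' Measures six-fold (hexagonal) symmetry of a spatial autocorrelogram. The
#' central peak (the contiguous region around the centre with correlation
#' above `peak_thresh`, at least 2 bins) is excised; for each outer annulus
#' radius in `radii` bins, the annulus is rotated in 30-degree increments by
#' bilinear interpolation, and the Pearson correlation between rotated and
#' unrotated annulus values is recorded. The interim score for a radius is
#' `min(corr at 60, 120) - max(corr at 30, 90, 150)`; the grid score is the
#' highest interim score across radii. Positive for hexagonal periodicity,
#' negative for square (90-degree) symmetry, near zero for radially
#' symmetric maps.
#'
#' @param sac autocorrelogram from [spatial_autocorrelogram()].
#' @param radii outer annulus radii in bins (expanding by 2 up to 20).
#' @param peak_thresh correlation threshold defining the central peak.
#' @param min_bins minimum valid annulus bins for a radius to count.
#' @return a `grid_score_result`: list with `grid_score`, `interim_scores`
#'   (one per usable radius, named by radius), `inner_radius`, `sac`.
#' @export
grid_score <- function(sac, radii = seq(8L, 20L, by = 2L),
                       peak_thresh = 0.3, min_bins = 20L) {
  S <- nrow(sac)
  ctr <- (S + 1L) %/% 2L
  ix <- row(sac) - ctr
  iy <- col(sac) - ctr
  dist <- sqrt(ix^2 + iy^2)
  # central peak: flood fill from the centre over sac > peak_thresh
  inner_r <- 2
  if (!is.na(sac[ctr, ctr]) && sac[ctr, ctr] > peak_thresh) {
    in_peak <- matrix(FALSE, S, S)
    queue <- list(c(ctr, ctr))
    in_peak[ctr, ctr] <- TRUE
    while (length(queue)) {
      cell <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i <- cell[1] + d[1]; j <- cell[2] + d[2]
        if (i >= 1 && i <= S && j >= 1 && j <= S && !in_peak[i, j] &&
            !is.na(sac[i, j]) && sac[i, j] > peak_thresh) {
          in_peak[i, j] <- TRUE
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
    inner_r <- max(2, max(dist[in_peak]))
  }
  angles <- c(30, 60, 90, 120, 150)
  interim <- numeric(0)
  for (R in radii) {
    if (R <= inner_r + 0.5) next
    ring <- which(dist > inner_r & dist <= R & !is.na(sac))
    if (length(ring) < min_bins) next
    u0 <- ix[ring]; v0 <- iy[ring]
    base <- sac[ring]
    cors <- rep(NA_real_, length(angles))
    for (ai in seq_along(angles)) {
      th <- angles[ai] * pi / 180
      # sample the sac at the coordinates rotated by -theta (equivalent to
      # rotating the annulus by +theta)
      ur <- cos(th) * u0 + sin(th) * v0
      vr <- -sin(th) * u0 + cos(th) * v0
      rot <- bilinear_sample(sac, ur + ctr, vr + ctr)
      ok <- !is.na(rot)
      if (sum(ok) < min_bins) next
      if (stats::sd(base[ok]) == 0 || stats::sd(rot[ok]) == 0) next
      cors[ai] <- stats::cor(base[ok], rot[ok])
    }
    if (any(is.na(cors))) next
    interim[as.character(R)] <- min(cors[c(2, 4)]) - max(cors[c(1, 3, 5)])
  }
  score <- if (length(interim)) max(interim) else NA_real_
  structure(list(grid_score = score, interim_scores = interim,
                 inner_radius = inner_r),
            class = "grid_score_result")
}

#' Synthetic periodic activation maps
#'
#' Analytic oracle fields for validating the grid-score pipeline: a
#' hexagonal field (sum of three cosine plane waves at 0/60/120 degrees,
#' which must score > 0.5), a square lattice (waves at 0/90 degrees, which
#' must score negative), a radially symmetric field (score near 0), and a
#' constant field (undefined autocorrelogram).
#'
#' @param lattice one of `"hexagonal"`, `"square"`, `"radial"`,
#'   `"constant"`.
#' @param wavelength field wavelength in bins (must be below `grid_size/2`).
#' @param amplitude wave amplitude.
#' @param grid_size map side length in bins.
#' @return an `activation_map` with uniform visit counts.
#' @export
synthetic_field <- function(lattice = c("hexagonal", "square", "radial",
                                        "constant"),
                            wavelength = 12, amplitude = 1,
                            grid_size = 40L) {
  lattice <- match.arg(lattice)
  B <- as.integer(grid_size)
  if (lattice != "constant" && !(wavelength < B / 2)) {
    stop("`wavelength` must be below grid_size / 2")
  }
  x <- matrix(rep(seq_len(B), B), B, B)
  y <- t(x)
  kmag <- 2 * pi / wavelength
  wave <- function(theta_deg) {
    th <- theta_deg * pi / 180
    cos(kmag * (cos(th) * x + sin(th) * y))
  }
  values <- switch(lattice,
    hexagonal = amplitude * (wave(0) + wave(60) + wave(120)),
    square = amplitude * (wave(0) + wave(90)),
    radial = {
      d <- sqrt((x - (B + 1) / 2)^2 + (y - (B + 1) / 2)^2)
      amplitude * cos(kmag * d)
    },
    constant = matrix(amplitude, B, B)
  )
  structure(list(values = values, visits = matrix(1L, B, B), bins = B),
            class = "activation_map")
}
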