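# Spectral preprocessing and similarity metrics: asymmetric-least-squares
# baseline correction, linear regridding, Pearson correlation of intensity
# vectors and the 1-D Wasserstein (optimal transport) distance between
# spectra treated as normalized distributions over wavenumber.

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a slowly varying baseline by penalized least squares with
#' asymmetric weights (points above the baseline, i.e. peaks, are
#' down-weighted by `p`), subtracts it and clips negative residuals at zero.
#'
#' @param spec a [new_spectrum()] with >= 10 points.
#' @param lambda smoothness penalty on second differences; default 1e5.
#' @param p asymmetry (weight of points above the baseline); default 0.01.
#' @param n_iter weight-update iterations; default 10.
#' @return baseline-corrected [new_spectrum()].
#' @export
baseline_correct <- function(spec, lambda = 1e5, p = 0.01, n_iter = 10) {
  stopifnot(inherits(spec, "spectrum"))
  y <- spec$intensities
  m <- length(y)
  if (m < 10) stop("baseline correction needs at least 10 points")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.vector(Matrix::solve(W + P, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  new_spectrum(spec$wavenumbers, pmax(y - z, 0))
}

#' Regrid a spectrum by linear interpolation
#'
#' Piecewise-linear interpolation onto `target` wavenumbers; points outside
#' the source support become 0 with a warning.
#'
#' @param spec a [new_spectrum()].
#' @param target strictly ascending wavenumber grid, cm^-1.
#' @return a [new_spectrum()] on `target`.
#' @export
regrid <- function(spec, target) {
  stopifnot(inherits(spec, "spectrum"))
  target <- as.numeric(target)
  rng <- range(spec$wavenumbers)
  if (max(target) < rng[1] || min(target) > rng[2])
    stop("target grid does not overlap the spectrum support")
  outside <- target < rng[1] | target > rng[2]
  if (any(outside))
    warning(sum(outside), " target point(s) outside the support set to 0")
  y <- stats::approx(spec$wavenumbers, spec$intensities, xout = target,
                     rule = 1)$y
  y[is.na(y)] <- 0
  new_spectrum(target, y)
}

#' Pearson correlation coefficient of two intensity vectors
#'
#' \deqn{PCC = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {\sqrt{\sum_i (x_i - \bar x)^2} \sqrt{\sum_i (y_i - \bar y)^2}}}
#'
#' @param x,y equal-length intensity vectors (>= 2 points, non-constant).
#' @return scalar in [-1, 1].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  cx <- x - mean(x); cy <- y - mean(y)
  den <- sqrt(sum(cx^2)) * sqrt(sum(cy^2))
  if (den == 0) stop("constant input: correlation undefined")
  max(-1, min(1, sum(cx * cy) / den))
}

#' 1-D Wasserstein distance between spectra
#'
#' Intensities are normalized to unit mass (distributions over the
#' wavenumber axis); the optimal-transport distance is then the L1 distance
#' between the inverse cumulative distribution functions, evaluated exactly
#' on the merged quantile levels of the two discrete distributions.
#'
#' @param x_grid,y_grid wavenumber supports, cm^-1.
#' @param x_int,y_int non-negative intensities with positive total mass.
#' @return transport distance, cm^-1.
#' @export
wasserstein <- function(x_grid, x_int, y_grid, y_int) {
  if (any(x_int < 0) || any(y_int < 0))
    stop("intensities must be non-negative")
  if (sum(x_int) <= 0 || sum(y_int) <= 0)
    stop("zero total mass: distribution undefined")
  ox <- order(x_grid); oy <- order(y_grid)
  xg <- x_grid[ox]; yg <- y_grid[oy]
  px <- x_int[ox] / sum(x_int)
  py <- y_int[oy] / sum(y_int)
  cx <- cumsum(px); cy <- cumsum(py)
  # merged quantile levels; inverse CDFs are piecewise constant between them
  q <- sort(unique(c(0, cx, cy)))
  q <- q[q < 1 - 1e-15]
  lev <- (q + c(q[-1], 1)) / 2          # representative level per interval
  wid <- c(q[-1], 1) - q
  invx <- xg[findInterval(lev, cx, left.open = TRUE) + 1L]
  invy <- yg[findInterval(lev, cy, left.open = TRUE) + 1L]
  sum(wid * abs(invx - invy))
}

#' Compare two spectra: PCC and Wasserstein distance on a common grid
#'
#' Optionally baseline-corrects the input designated as experimental
#' (`b`), then regrids `a` onto `b`'s grid and evaluates both metrics.
#'
#' @param a "theoretical" [new_spectrum()] (regridded onto `b`).
#' @param b "experimental" [new_spectrum()] (optionally baseline-corrected).
#' @param do_baseline apply [baseline_correct()] to `b`; default FALSE.
#' @return list of class `similarity_report`: `pcc`, `wd` (cm^-1), `grid`.
#' @export
compare_spectra <- function(a, b, do_baseline = FALSE) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (do_baseline) b <- baseline_correct(b)
  ar <- suppressWarnings(regrid(a, b$wavenumbers))
  structure(list(
    pcc = pcc(ar$intensities, b$intensities),
    wd = wasserstein(ar$wavenumbers, ar$intensities,
                     b$wavenumbers, b$intensities),
    grid = b$wavenumbers), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity: PCC = %.4f, WD = %.2f cm^-1 (%d grid points)>\n",
              x$pcc, x$wd, length(x$grid)))
  invisible(x)
}
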