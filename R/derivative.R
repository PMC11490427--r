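#' Negative first derivative of a melt curve
#'
#' Melting transitions appear as peaks in -dF/dT. The raw derivative is the
#' finite difference -(F[i+1] - F[i]) / (T[i+1] - T[i]) placed at interval
#' midpoints, then smoothed with a Savitzky-Golay local polynomial filter on
#' the midpoint grid. On the canonical 0.1 degC ramp the midpoint grid runs
#' 60.05, 60.15, ..., 94.95, which makes 64.95 degC — the pad temperature used
#' by the feature extractor — a native grid point.
#'
#' Negative values are not clipped: small negative excursions are ordinary
#' instrument noise and clipping would bias the smoother.
#'
#' @param curve A [melt_curve()].
#' @param window Odd number of points in the smoothing window; `window = 1`
#'   disables smoothing and returns the raw finite differences.
#' @param degree Polynomial degree of the smoother; must satisfy
#'   `window >= degree + 2` when smoothing is on.
#' @return A `"derivative_curve"` list with fields `midpoint_temperatures`,
#'   `neg_dFdT`, `smoothed`, and the originating `sample_id` / `locus`.
#' @export
compute_derivative <- function(curve, window = 11L, degree = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  window <- as.integer(window)
  degree <- as.integer(degree)
  if (window %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  if (window > 1L && window < degree + 2L) {
    stop("smoothing window must be >= degree + 2", call. = FALSE)
  }
  if (length(curve$temperatures) <= window) {
    stop("curve shorter than the smoothing window", call. = FALSE)
  }
  dT <- diff(curve$temperatures)
  raw <- -diff(curve$fluorescence) / dT
  mid <- curve$temperatures[-length(curve$temperatures)] + dT / 2
  if (window == 1L) {
    y <- raw
    smoothed <- FALSE
  } else {
    y <- signal::sgolayfilt(raw, p = degree, n = window)
    smoothed <- TRUE
  }
  structure(
    list(sample_id = curve$sample_id, locus = curve$locus,
         midpoint_temperatures = mid, neg_dFdT = y, smoothed = smoothed),
    class = "derivative_curve"
  )
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("<derivative_curve %s @ %s: %d points%s>\n",
              x$sample_id, x$locus, length(x$neg_dFdT),
              if (x$smoothed) ", smoothed" else ", raw"))
  invisible(x)
}
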