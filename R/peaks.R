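#' Peak-detection configuration
#'
#' @param melt_window Length-2 numeric, the temperature interval (degC) in
#'   which melting transitions are sought.
#' @param prominence_frac Resolved peaks must have topographic prominence at
#'   least this fraction of the tallest -dF/dT value inside the window.
#' @param terrace_frac A flank flattening counts as an unresolved shoulder
#'   when the local slope magnitude falls to at most this fraction of the
#'   flank's maximum slope magnitude.
#' @return A `"peak_config"` list.
#' @export
peak_config <- function(melt_window = c(70, 90), prominence_frac = 0.05,
                        terrace_frac = 0.15) {
  stopifnot(length(melt_window) == 2L, melt_window[1L] < melt_window[2L],
            prominence_frac > 0, terrace_frac > 0)
  structure(list(melt_window = as.numeric(melt_window),
                 prominence_frac = prominence_frac,
                 terrace_frac = terrace_frac),
            class = "peak_config")
}

# Topographic prominence of the local maximum at index i of y: walk out on
# each side until a strictly higher point or the series edge; the key saddle
# is the higher of the two minima encountered.
.prominence <- function(y, i) {
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) {
    left_min <- min(left_min, y[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(left_min, min(y[seq_len(i)]))
  right_min <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) {
    right_min <- min(right_min, y[j])
    j <- j + 1L
  }
  if (j > length(y)) right_min <- min(right_min, min(y[i:length(y)]))
  h - max(left_min, right_min)
}

.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0L))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

#' Detect the primary melt peak and its shoulders
#'
#' Identifies, on a smoothed negative-derivative curve, the observations that
#' summarize a sample's melt morphology:
#' \enumerate{
#'   \item Resolved peaks: local maxima of -dF/dT inside `melt_window` whose
#'     topographic prominence is at least `prominence_frac` times the tallest
#'     in-window value. The tallest candidate is the primary (ties go to the
#'     lower temperature); the rest are resolved shoulders.
#'   \item Unresolved shoulders: terraces on the primary's flanks. With
#'     `g` the first difference of the smoothed curve, an interior local
#'     minimum of `g` on the ascending flank with `0 < g <= terrace_frac *
#'     max(g)` marks a terrace; symmetrically on the descending flank, an
#'     interior local maximum of `g` with `g < 0` and `|g| <= terrace_frac *
#'     max|g|`.
#' }
#' Heights are read from the smoothed curve at the detected temperatures.
#'
#' @param dcurve A smoothed `derivative_curve` from [compute_derivative()].
#' @param cfg A [peak_config()].
#' @return A data frame of observations with columns `temperature`, `height`,
#'   `kind`; the primary first, then shoulders by ascending temperature.
#' @export
detect_peaks <- function(dcurve, cfg = peak_config()) {
  stopifnot(inherits(dcurve, "derivative_curve"), inherits(cfg, "peak_config"))
  t_all <- dcurve$midpoint_temperatures
  y_all <- dcurve$neg_dFdT
  in_win <- which(t_all >= cfg$melt_window[1L] & t_all <= cfg$melt_window[2L])
  if (length(in_win) < 3L) {
    stop("melt window contains too few grid points", call. = FALSE)
  }
  tw <- t_all[in_win]
  yw <- y_all[in_win]
  ymax <- max(yw)
  cand <- .local_maxima(yw)
  cand <- cand[vapply(cand, function(i) .prominence(yw, i), numeric(1L)) >=
                 cfg$prominence_frac * ymax]
  if (length(cand) == 0L) {
    stop(sprintf("sample '%s': no melt peak found inside [%g, %g] degC",
                 dcurve$sample_id, cfg$melt_window[1L], cfg$melt_window[2L]),
         call. = FALSE)
  }
  # primary = tallest; tie -> lower temperature (candidates are T-ordered)
  prim <- cand[which.max(yw[cand])]
  resolved <- setdiff(cand, prim)

  obs <- data.frame(temperature = tw[prim], height = yw[prim],
                    kind = "primary", stringsAsFactors = FALSE)
  if (length(resolved) > 0L) {
    obs <- rbind(obs, data.frame(temperature = tw[resolved],
                                 height = yw[resolved],
                                 kind = "shoulder_resolved",
                                 stringsAsFactors = FALSE))
  }

  # terrace test on the primary's flanks
  g <- diff(yw)                       # g[i] spans tw[i] .. tw[i+1]
  add_terrace <- function(idx_set, asc) {
    if (length(idx_set) < 3L) return(NULL)
    gg <- g[idx_set]
    if (asc) {
      cap <- cfg$terrace_frac * max(gg)
      hits <- which(gg[2:(length(gg) - 1L)] < gg[1:(length(gg) - 2L)] &
                    gg[2:(length(gg) - 1L)] <= gg[3:length(gg)]) + 1L
      hits <- hits[gg[hits] > 0 & gg[hits] <= cap]
    } else {
      cap <- cfg$terrace_frac * max(abs(gg[gg < 0]), 0)
      hits <- which(gg[2:(length(gg) - 1L)] > gg[1:(length(gg) - 2L)] &
                    gg[2:(length(gg) - 1L)] >= gg[3:length(gg)]) + 1L
      hits <- hits[gg[hits] < 0 & abs(gg[hits]) <= cap]
    }
    if (length(hits) == 0L) return(NULL)
    i <- idx_set[hits]
    temp <- (tw[i] + tw[i + 1L]) / 2
    data.frame(temperature = temp,
               height = stats::approx(tw, yw, xout = temp)$y,
               kind = "shoulder_unresolved", stringsAsFactors = FALSE)
  }
  asc_idx <- seq_len(max(prim - 1L, 0L))                 # g indices left of primary
  dsc_idx <- if (prim <= length(g)) prim:length(g) else integer(0L)
  obs <- rbind(obs, add_terrace(asc_idx, asc = TRUE),
               add_terrace(dsc_idx, asc = FALSE))

  shoulders <- obs[obs$kind != "primary", , drop = FALSE]
  shoulders <- shoulders[order(shoulders$temperature), , drop = FALSE]
  out <- rbind(obs[obs$kind == "primary", , drop = FALSE], shoulders)
  rownames(out) <- NULL
  out
}
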