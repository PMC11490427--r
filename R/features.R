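#' Fixed-length feature vector for one sample
#'
#' Classifiers require every sample to contribute the same number of
#' observations, but melt curves show anywhere from one to several peaks and
#' shoulders. The feature vector therefore has a fixed length `k` (3 for
#' D5S818, 4 for D18S51):
#' \itemize{
#'   \item more than `k` observations: the primary plus the `k - 1` tallest
#'     shoulders are kept;
#'   \item fewer than `k`: pad observations are appended at 64.95 degC — a
#'     native point of the canonical midpoint grid, safely below any melting
#'     transition — with height equal to the smoothed -dF/dT there.
#' }
#' The flattened layout is `(T1, h1, ..., Tk, hk)`, primary first, then
#' shoulders by ascending temperature, pads last.
#'
#' @param peaks Observation data frame from [detect_peaks()] (>= 1 row).
#' @param dcurve The smoothed `derivative_curve` the peaks came from (needed
#'   to read the pad height).
#' @param k Target observation count, 3 or 4.
#' @param pad_temperature Pad temperature in degC.
#' @return A list with `sample_id`, `locus`, `values` (numeric, length
#'   `2 * k`), and `kinds` (character, length `k`).
#' @export
extract_features <- function(peaks, dcurve, k, pad_temperature = 64.95) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1L, k %in% c(3L, 4L))
  k <- as.integer(k)
  prim <- peaks[peaks$kind == "primary", , drop = FALSE]
  if (nrow(prim) != 1L) stop("exactly one primary observation required", call. = FALSE)
  sh <- peaks[peaks$kind != "primary", , drop = FALSE]
  if (nrow(sh) > k - 1L) {
    # keep the tallest shoulders; ties broken toward lower temperature
    keep <- order(-sh$height, sh$temperature)[seq_len(k - 1L)]
    sh <- sh[keep, , drop = FALSE]
  }
  sh <- sh[order(sh$temperature), , drop = FALSE]
  obs <- rbind(prim, sh)
  n_pad <- k - nrow(obs)
  if (n_pad > 0L) {
    tm <- dcurve$midpoint_temperatures
    if (pad_temperature < min(tm) || pad_temperature > max(tm)) {
      stop(sprintf("pad temperature %.2f degC lies outside the curve's range",
                   pad_temperature), call. = FALSE)
    }
    pad_h <- stats::approx(tm, dcurve$neg_dFdT, xout = pad_temperature)$y
    obs <- rbind(obs, data.frame(temperature = rep(pad_temperature, n_pad),
                                 height = rep(pad_h, n_pad),
                                 kind = rep("pad", n_pad),
                                 stringsAsFactors = FALSE))
  }
  values <- as.numeric(t(as.matrix(obs[, c("temperature", "height")])))
  names(values) <- paste0(rep(c("T", "h"), k), rep(seq_len(k), each = 2L))
  list(sample_id = dcurve$sample_id, locus = dcurve$locus,
       values = values, kinds = obs$kind)
}

#' Run the feature pipeline over a set of melt curves
#'
#' Convenience wrapper: derivative, smoothing, peak/shoulder detection and
#' fixed-length feature extraction for each curve, assembled into one feature
#' table. Curves in which no peak is detected are dropped with a warning and
#' listed in the `"failed"` attribute.
#'
#' @param curves List of [melt_curve()] objects.
#' @param k Observations per sample (3 or 4).
#' @param metadata Optional metadata data frame (from
#'   [read_sample_metadata()]); adds the `genotype` and `role` columns.
#' @param window,degree Savitzky-Golay parameters for [compute_derivative()].
#' @param cfg [peak_config()] used for detection.
#' @return Data frame: `sample_id`, `locus`, `genotype`, `role`, `T1`, `h1`,
#'   ..., `Tk`, `hk`, `kinds`.
#' @export
curves_to_features <- function(curves, k, metadata = NULL,
                               window = 11L, degree = 3L,
                               cfg = peak_config()) {
  rows <- list()
  failed <- character(0L)
  for (cu in curves) {
    fv <- tryCatch({
      d <- compute_derivative(cu, window = window, degree = degree)
      extract_features(detect_peaks(d, cfg), d, k)
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      failed <- c(failed, cu$sample_id)
      next
    }
    row <- data.frame(sample_id = fv$sample_id, locus = fv$locus,
                      stringsAsFactors = FALSE)
    for (nm in names(fv$values)) row[[nm]] <- fv$values[[nm]]
    row$kinds <- paste(fv$kinds, collapse = ",")
    rows[[length(rows) + 1L]] <- row
  }
  if (length(failed) > 0L) {
    warning(sprintf("no peak detected for %d sample(s): %s", length(failed),
                    paste(failed, collapse = ", ")), call. = FALSE)
  }
  if (length(rows) == 0L) stop("no usable curves", call. = FALSE)
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    idx <- match(out$sample_id, metadata$sample_id)
    out$genotype <- metadata$genotype[idx]
    out$role <- metadata$role[idx]
    out <- out[, c("sample_id", "locus", "genotype", "role",
                   setdiff(names(out), c("sample_id", "locus", "genotype", "role")))]
  }
  attr(out, "failed") <- failed
  rownames(out) <- NULL
  out
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features Feature table from [curves_to_features()].
#' @return Numeric matrix, one row per sample, columns `T1,h1,...,Tk,hk`.
#' @export
feature_matrix <- function(features) {
  cols <- grep("^[Th][0-9]+$", names(features), value = TRUE)
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$sample_id
  m
}
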