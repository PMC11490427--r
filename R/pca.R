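#' Normalize a derivative curve for PCA typing
#'
#' Restricts the smoothed -dF/dT to the melt window and min-max scales it to
#' `[0, 1]`. Differentiation already removes additive baselines; the min-max
#' scaling removes amplitude differences, so typing responds to melt-peak
#' shape only.
#'
#' @param dcurve A `derivative_curve` from [compute_derivative()].
#' @param melt_window Length-2 numeric temperature interval (degC).
#' @return List with `grid` (midpoint temperatures inside the window) and
#'   `values` (normalized -dF/dT, min 0 and max 1), plus `sample_id`/`locus`.
#' @export
normalize_curve <- function(dcurve, melt_window = c(70, 90)) {
  stopifnot(inherits(dcurve, "derivative_curve"), length(melt_window) == 2L)
  tm <- dcurve$midpoint_temperatures
  if (melt_window[1L] < min(tm) || melt_window[2L] > max(tm)) {
    stop("melt window extends beyond the curve's temperature range", call. = FALSE)
  }
  sel <- tm >= melt_window[1L] & tm <= melt_window[2L]
  y <- dcurve$neg_dFdT[sel]
  rng <- range(y)
  if (rng[2L] - rng[1L] <= 0) {
    stop(sprintf("sample '%s': no melt signal (flat derivative in window)",
                 dcurve$sample_id), call. = FALSE)
  }
  list(sample_id = dcurve$sample_id, locus = dcurve$locus,
       grid = tm[sel], values = (y - rng[1L]) / (rng[2L] - rng[1L]))
}

#' PCA-based genotype typing of melt curves
#'
#' A fully specified analogue of proprietary PCA cluster-typing software:
#' normalized derivative curves of the standards are centered and projected
#' onto the top `m` principal components, a Gaussian is fitted to each
#' class's scores (covariance pooled across classes by default — 7-10
#' standards per genotype cannot support stable per-class covariances), and
#' unknowns are assigned to the class with the highest posterior density,
#' unless the Mahalanobis distance to even the best class exceeds the
#' chi-squared(`m`) quantile `typing_quantile`, in which case the sample is
#' `"UNCLASSIFIED"`. Unlike instrument-bound software, the fitted model can
#' be serialized and reused without re-running the standards.
#'
#' Loadings are computed by singular value decomposition of the centered
#' standards matrix; each component's sign is fixed so its largest-magnitude
#' entry is positive.
#'
#' @param curves List of normalized curves from [normalize_curve()], all on
#'   one grid.
#' @param labels Class label per curve; >= 2 standards per class.
#' @param m Number of principal components (1 <= m < number of standards).
#' @param typing_quantile Chi-squared quantile for the unclassified cutoff.
#' @param pooled Pool the score covariance across classes (default) or fit
#'   per-class covariances.
#' @return A `"pca_model"` list: `grid`, `mean_curve`, `loadings` (p x m,
#'   orthonormal), `explained_variance` (non-increasing), `class_gaussians`,
#'   `m`, `typing_quantile`, `pooled`.
#' @export
fit_pca_typing <- function(curves, labels, m = 2L, typing_quantile = 0.999,
                           pooled = TRUE) {
  labels <- as.character(labels)
  n <- length(curves)
  stopifnot(n == length(labels), n >= 2L)
  m <- as.integer(m)
  if (m < 1L || m >= n) stop("need 1 <= m < number of standards", call. = FALSE)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop(sprintf("class(es) with fewer than 2 standards: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")), call. = FALSE)
  }
  grid <- curves[[1L]]$grid
  X <- t(vapply(curves, function(cu) {
    if (length(cu$grid) != length(grid) || any(abs(cu$grid - grid) > 1e-9)) {
      stop("all standards must share one temperature grid", call. = FALSE)
    }
    cu$values
  }, numeric(length(grid))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = m)
  loadings <- sv$v
  # sign convention: largest-|entry| coordinate positive
  for (j in seq_len(m)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  expl_var <- (sv$d[seq_len(m)]^2) / (n - 1L)
  scores <- Xc %*% loadings
  gaussians <- list()
  pooled_cov <- matrix(0, m, m)
  for (cl in classes) {
    sc <- scores[labels == cl, , drop = FALSE]
    ctr <- colMeans(sc)
    dev <- sweep(sc, 2L, ctr)
    gaussians[[cl]] <- list(mean = ctr, cov = crossprod(dev) / (nrow(sc) - 1L))
    pooled_cov <- pooled_cov + crossprod(dev)
  }
  pooled_cov <- pooled_cov / (n - length(classes))
  if (pooled) for (cl in classes) gaussians[[cl]]$cov <- pooled_cov
  structure(
    list(grid = grid, mean_curve = mu, loadings = loadings,
         explained_variance = expl_var, class_gaussians = gaussians,
         m = m, typing_quantile = typing_quantile, pooled = pooled),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d classes, m = %d, typing quantile %g>\n",
              length(x$class_gaussians), x$m, x$typing_quantile))
  invisible(x)
}

#' Type an unknown sample with a fitted PCA model
#'
#' @param model A `pca_model` from [fit_pca_typing()].
#' @param curve A normalized curve on the model's grid.
#' @return List with `label` (class label or `"UNCLASSIFIED"`), `posterior`
#'   (named vector, uniform class priors), and `mahalanobis` (distance to the
#'   best class in score space).
#' @export
type_unknown <- function(model, curve) {
  stopifnot(inherits(model, "pca_model"))
  if (length(curve$grid) != length(model$grid) ||
      any(abs(curve$grid - model$grid) > 1e-9)) {
    stop("curve grid does not match the model grid", call. = FALSE)
  }
  s <- as.numeric((curve$values - model$mean_curve) %*% model$loadings)
  classes <- names(model$class_gaussians)
  logd <- d2 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    g <- model$class_gaussians[[ci]]
    dv <- s - g$mean
    ic <- solve(g$cov)
    d2[ci] <- as.numeric(dv %*% ic %*% dv)
    logd[ci] <- -0.5 * (d2[ci] + determinant(g$cov)$modulus[[1L]] +
                          model$m * log(2 * pi))
  }
  z <- logd - max(logd)
  post <- exp(z) / sum(exp(z))
  names(post) <- classes
  best <- which.max(logd)                     # tie -> class-label order
  cutoff <- stats::qchisq(model$typing_quantile, df = model$m)
  label <- if (d2[best] > cutoff) "UNCLASSIFIED" else classes[best]
  list(label = label, posterior = post, mahalanobis = sqrt(d2[best]))
}

#' Serialize / restore a PCA typing model as JSON
#'
#' @param model A `pca_model`.
#' @param path JSON file path.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  cm <- vapply(model$class_gaussians, `[[`, numeric(model$m), "mean")
  cm <- if (model$m == 1L) matrix(cm, ncol = 1L) else t(cm)
  obj <- list(grid = model$grid, mean_curve = model$mean_curve,
              loadings = model$loadings,
              explained_variance = model$explained_variance,
              classes = names(model$class_gaussians),
              class_means = cm,
              class_covs = lapply(model$class_gaussians, `[[`, "cov"),
              m = model$m, typing_quantile = model$typing_quantile,
              pooled = model$pooled)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$m
  gaussians <- list()
  for (i in seq_along(obj$classes)) {
    cv <- obj$class_covs[[i]]
    if (!is.matrix(cv)) cv <- matrix(as.numeric(cv), m, m)
    gaussians[[obj$classes[i]]] <-
      list(mean = as.numeric(obj$class_means[i, ]), cov = cv)
  }
  structure(
    list(grid = as.numeric(obj$grid), mean_curve = as.numeric(obj$mean_curve),
         loadings = as.matrix(obj$loadings),
         explained_variance = as.numeric(obj$explained_variance),
         class_gaussians = gaussians, m = m,
         typing_quantile = obj$typing_quantile, pooled = obj$pooled),
    class = "pca_model"
  )
}
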