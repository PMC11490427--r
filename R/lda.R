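#' Linear discriminant analysis for melt-curve features
#'
#' Fits the classical LDA model from its defining statistics: per-class mean
#' vectors and a pooled within-class covariance,
#' \deqn{\Sigma_W = \sum_c \sum_{i \in c} (x_i - \mu_c)(x_i - \mu_c)^T / (n - C),}
#' ridge-stabilized as \eqn{\Sigma_\lambda = \Sigma_W + \lambda\,
#' \mathrm{diag}(\Sigma_W)}. Classification uses the linear discriminant
#' \deqn{\delta_c(x) = x^T \Sigma_\lambda^{-1} \mu_c - \tfrac12 \mu_c^T
#' \Sigma_\lambda^{-1} \mu_c + \ln \pi_c,}
#' the Gaussian log-posterior under equal class covariances with the
#' quadratic term (shared by all classes) dropped.
#'
#' The relative ridge keeps the solve well-posed when a feature column is
#' (near-)constant — notably the pad temperature column, fixed at 64.95 degC
#' whenever every training sample was padded. A column with exactly zero
#' variance gets \eqn{\lambda} times the mean positive diagonal instead,
#' since scaling a zero diagonal entry would add nothing.
#'
#' @param x Numeric matrix, one row per training sample.
#' @param labels Class labels (one per row); every class needs >= 2 samples.
#' @param priors `"uniform"` (default; the study benchmarks against the
#'   1-in-C chance rate, implying no prior weighting) or `"empirical"`
#'   (class frequencies), or a named numeric vector summing to 1.
#' @param ridge Relative ridge \eqn{\lambda \ge 0}.
#' @return An `"lda_model"` list: `class_labels`, `class_means` (C x p),
#'   `pooled_covariance`, `priors`, `ridge`, `feature_dim`.
#' @export
fit_lda <- function(x, labels, priors = "uniform", ridge = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), ridge >= 0)
  classes <- sort(unique(labels))
  C <- length(classes)
  n <- nrow(x)
  p <- ncol(x)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (n <= C) stop("need more samples than classes", call. = FALSE)
  counts <- table(factor(labels, levels = classes))
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    stop(sprintf("class(es) with fewer than 2 samples: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  means <- matrix(0, C, p, dimnames = list(classes, colnames(x)))
  S <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    xc <- x[labels == classes[ci], , drop = FALSE]
    means[ci, ] <- colMeans(xc)
    dev <- sweep(xc, 2L, means[ci, ])
    S <- S + crossprod(dev)
  }
  sigma_w <- S / (n - C)
  d <- diag(sigma_w)
  if (all(d <= 0)) stop("all features are constant; nothing to discriminate",
                        call. = FALSE)
  ridge_diag <- d
  ridge_diag[d <= 0] <- mean(d[d > 0])
  sigma_l <- sigma_w + ridge * diag(ridge_diag, p)
  ev <- eigen(sigma_l, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("pooled covariance is singular; refit with ridge > 0", call. = FALSE)
  }
  pri <- if (identical(priors, "uniform")) {
    rep(1 / C, C)
  } else if (identical(priors, "empirical")) {
    as.numeric(counts) / n
  } else {
    stopifnot(is.numeric(priors), length(priors) == C,
              abs(sum(priors) - 1) < 1e-8)
    as.numeric(priors[classes])
  }
  names(pri) <- classes
  structure(
    list(class_labels = classes, class_means = means,
         pooled_covariance = sigma_w, ridged_covariance = sigma_l,
         priors = pri, ridge = ridge, feature_dim = p),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: %d classes, %d features, ridge %g>\n",
              length(x$class_labels), x$feature_dim, x$ridge))
  invisible(x)
}

#' Predict genotypes with a fitted LDA model
#'
#' @param model An `lda_model` from [fit_lda()].
#' @param x Numeric vector (one sample) or matrix (one row per sample) of
#'   feature vectors; dimension must match the model.
#' @return A list with `label` (character vector of argmax classes, ties
#'   broken by class-label order) and `posterior` (matrix of softmax-
#'   normalized discriminant scores, rows summing to 1).
#' @export
predict_lda <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$feature_dim) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(x), model$feature_dim), call. = FALSE)
  }
  inv_mu <- solve(model$ridged_covariance, t(model$class_means))  # p x C
  const <- -0.5 * colSums(t(model$class_means) * inv_mu) + log(model$priors)
  scores <- x %*% inv_mu + matrix(const, nrow(x), length(const), byrow = TRUE)
  colnames(scores) <- model$class_labels
  # softmax with max-subtraction for stability
  z <- scores - apply(scores, 1L, max)
  post <- exp(z) / rowSums(exp(z))
  lab <- model$class_labels[apply(scores, 1L, which.max)]  # which.max: first max wins
  list(label = lab, posterior = post)
}

#' Serialize / restore an LDA model as JSON
#'
#' Full double precision is written, so a round trip restores the model
#' exactly to the printed digits (15 significant).
#'
#' @param model An `lda_model`.
#' @param path JSON file path.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(class_labels = model$class_labels,
              class_means = model$class_means,
              pooled_covariance = model$pooled_covariance,
              priors = as.numeric(model$priors),
              ridge = model$ridge, feature_dim = model$feature_dim)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- matrix(as.numeric(obj$class_means), nrow = length(obj$class_labels),
                  byrow = FALSE)
  if (is.matrix(obj$class_means)) means <- obj$class_means
  sigma_w <- obj$pooled_covariance
  p <- obj$feature_dim
  d <- diag(sigma_w)
  ridge_diag <- d
  ridge_diag[d <= 0] <- mean(d[d > 0])
  sigma_l <- sigma_w + obj$ridge * diag(ridge_diag, p)
  pri <- as.numeric(obj$priors)
  names(pri) <- obj$class_labels
  rownames(means) <- obj$class_labels
  structure(
    list(class_labels = obj$class_labels, class_means = means,
         pooled_covariance = sigma_w, ridged_covariance = sigma_l,
         priors = pri, ridge = obj$ridge, feature_dim = p),
    class = "lda_model"
  )
}
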