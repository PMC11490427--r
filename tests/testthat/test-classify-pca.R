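# Toy normalized-curve builders on a short grid.
toy_curve <- function(values, grid = seq(70, 90, length.out = length(values)),
                      id = "t") {
  list(sample_id = id, locus = "TEST", grid = grid, values = values)
}

test_that("normalization maps curves to [0, 1] and kills scale and baseline", {
  cu <- logistic_curve(78, 1000, slope = 0.3)
  d <- compute_derivative(cu)
  nc <- normalize_curve(d)
  expect_equal(min(nc$values), 0)
  expect_equal(max(nc$values), 1)
  expect_true(all(nc$grid >= 70 & nc$grid <= 90))
  # 10x amplitude: identical normalized output
  cu10 <- logistic_curve(78, 10000, slope = 0.3)
  nc10 <- normalize_curve(compute_derivative(cu10))
  expect_equal(nc10$values, nc$values, tolerance = 1e-9)
  # +500 additive baseline: identical (the derivative removes constants)
  cub <- melt_curve("b", "TEST", cu$temperatures, cu$fluorescence + 500)
  expect_equal(normalize_curve(compute_derivative(cub))$values, nc$values,
               tolerance = 1e-9)
  flat <- melt_curve("f", "TEST", canonical_grid(), rep(3, 351))
  expect_error(normalize_curve(compute_derivative(flat)), "no melt signal")
})

test_that("PCA typing fit satisfies its structural invariants", {
  set.seed(61)
  mk <- function(center, id) toy_curve(pmin(pmax(
    exp(-(seq(70, 90, 0.5) - center)^2 / 2) + rnorm(41, 0, 0.02), 0), 1), id = id)
  curves <- c(lapply(1:6, function(i) mk(76, i)),
              lapply(7:12, function(i) mk(84, i)))
  labels <- rep(c("a", "b"), each = 6L)
  m <- fit_pca_typing(curves, labels, m = 2L)
  expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  # duplicated standards: identical loadings and class Gaussians
  m2 <- fit_pca_typing(c(curves, curves), c(labels, labels), m = 2L)
  expect_equal(m2$loadings, m$loadings)
  expect_equal(m2$class_gaussians$a$mean, m$class_gaussians$a$mean)
  # order of standards is irrelevant
  perm <- sample(12L)
  m3 <- fit_pca_typing(curves[perm], labels[perm], m = 2L)
  expect_equal(m3$loadings, m$loadings)
  expect_equal(m3$class_gaussians, m$class_gaussians)
  expect_error(fit_pca_typing(curves, labels, m = 12L), "m <")
  expect_error(fit_pca_typing(curves[1:3], c("a", "a", "b"), m = 1L),
               "fewer than 2 standards")
})

test_that("full-rank reconstruction recovers the centered standards", {
  set.seed(71)
  curves <- lapply(1:8, function(i) toy_curve(runif(20), id = i))
  m <- fit_pca_typing(curves, rep(c("a", "b"), each = 4L), m = 7L)
  X <- t(vapply(curves, `[[`, numeric(20L), "values"))
  Xc <- sweep(X, 2L, m$mean_curve)
  scores <- Xc %*% m$loadings
  expect_equal(scores %*% t(m$loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("eigenvalues match a brute-force covariance eigendecomposition", {
  set.seed(81)
  curves <- lapply(1:10, function(i) toy_curve(runif(15), id = i))
  m <- fit_pca_typing(curves, rep(c("a", "b"), each = 5L), m = 4L)
  X <- t(vapply(curves, `[[`, numeric(15L), "values"))
  mu <- colMeans(X)
  S <- matrix(0, 15L, 15L)
  for (i in 1:10) S <- S + tcrossprod(X[i, ] - mu)
  S <- S / 9
  ev <- eigen(S, symmetric = TRUE)$values
  expect_equal(m$explained_variance, ev[1:4], tolerance = 1e-8)
})

test_that("typing assigns centroids to their class and flags outliers", {
  set.seed(91)
  grid <- seq(70, 90, 0.5)
  mk <- function(center, id) toy_curve(
    exp(-(grid - center)^2 / 2) + rnorm(41, 0, 0.01), id = id)
  curves <- c(lapply(1:8, function(i) mk(75, i)),
              lapply(9:16, function(i) mk(80, i)),
              lapply(17:24, function(i) mk(85, i)))
  labels <- rep(c("a", "b", "c"), each = 8L)
  model <- fit_pca_typing(curves, labels, m = 2L)
  # a class's own average curve types to that class with top posterior
  for (cl in c("a", "b", "c")) {
    avg <- colMeans(t(vapply(curves[labels == cl], `[[`, numeric(41L), "values")))
    r <- type_unknown(model, toy_curve(avg, grid))
    expect_equal(r$label, cl)
    expect_equal(names(which.max(r$posterior)), cl)
    expect_true(all(abs(sum(r$posterior) - 1) < 1e-12))
  }
  # an absurdly distant curve is UNCLASSIFIED
  far <- toy_curve(1e3 * sin(seq_along(grid)), grid)
  expect_equal(type_unknown(model, far)$label, "UNCLASSIFIED")
  expect_error(type_unknown(model, toy_curve(runif(10))), "grid")
})

test_that("typing posteriors match a brute-force density oracle", {
  set.seed(101)
  grid <- seq(70, 90, 0.5)
  mk <- function(center, id) toy_curve(
    exp(-(grid - center)^2 / 3) + rnorm(41, 0, 0.05), id = id)
  curves <- c(lapply(1:7, function(i) mk(76, i)),
              lapply(8:14, function(i) mk(82, i)))
  model <- fit_pca_typing(curves, rep(c("a", "b"), each = 7L), m = 2L)
  for (rep_i in 1:100) {
    u <- toy_curve(exp(-(grid - runif(1, 74, 84))^2 / 3) + rnorm(41, 0, 0.05),
                   grid)
    got <- type_unknown(model, u)
    # oracle: explicit Gaussian log-densities over the projected scores
    s <- as.numeric((u$values - model$mean_curve) %*% model$loadings)
    logdens <- vapply(model$class_gaussians, function(g) {
      ic <- chol2inv(chol(g$cov))
      dv <- s - g$mean
      q <- sum(vapply(1:2, function(i) sum(dv[i] * ic[i, ] * dv), numeric(1L)))
      -0.5 * q - 0.5 * log((2 * pi)^2 * det(g$cov))
    }, numeric(1L))
    want <- exp(logdens - max(logdens))
    expect_equal(as.numeric(got$posterior), as.numeric(want / sum(want)),
                 tolerance = 1e-8)
  }
})

test_that("typing separates well-separated simulated genotypes", {
  spec <- str_locus("D5S818")
  ds <- simulate_dataset(spec, n_standards = 8L, n_unknowns = 15L,
                         cfg = separated_config(), seed = 5)
  norm <- lapply(ds$curves, function(cu) normalize_curve(compute_derivative(cu)))
  std <- ds$metadata$role == "standard"
  model <- fit_pca_typing(norm[std], ds$metadata$genotype[std], m = 2L)
  pred <- vapply(norm[!std], function(cu) type_unknown(model, cu)$label,
                 character(1L))
  expect_gte(mean(pred == ds$metadata$genotype[!std]), 0.9)
})

test_that("typing on structureless noise sits near chance", {
  set.seed(111)
  grid <- seq(70, 90, 0.5)
  mk <- function(id) toy_curve(runif(41), id = id)
  curves <- lapply(1:40, mk)
  labels <- rep(c("a", "b", "c", "d"), each = 10L)
  model <- fit_pca_typing(curves, labels, m = 2L, typing_quantile = 1 - 1e-12)
  pred <- vapply(lapply(41:140, mk), function(cu) type_unknown(model, cu)$label,
                 character(1L))
  truth <- sample(c("a", "b", "c", "d"), 100L, replace = TRUE)
  expect_lt(abs(mean(pred == truth) - 0.25), 0.15)
})

test_that("PCA models round-trip through JSON", {
  set.seed(121)
  curves <- lapply(1:10, function(i) toy_curve(runif(12), id = i))
  m <- fit_pca_typing(curves, rep(c("a", "b"), each = 5L), m = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, path)
  m2 <- read_pca_model(path)
  u <- toy_curve(runif(12), m$grid)
  expect_equal(type_unknown(m2, u)$posterior, type_unknown(m, u)$posterior,
               tolerance = 1e-12)
  expect_equal(type_unknown(m2, u)$label, type_unknown(m, u)$label)
})
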