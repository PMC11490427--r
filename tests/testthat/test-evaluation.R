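rand_cm <- function(labels, seed) {
  set.seed(seed)
  n <- length(labels)
  m <- matrix(rpois(n * n, 3), n, n, dimnames = list(labels, labels))
  m[1L, 1L] <- m[1L, 1L] + 1L  # ensure positive total
  as_confusion(m)
}

test_that("build_confusion counts known x predicted pairs", {
  known <- rep(c("a", "b"), each = 5L)
  cm <- build_confusion(known, known, c("a", "b"))
  expect_equal(sum(diag(unclass(cm))), 10L)
  expect_equal(accuracy(cm), 1.0)
  expect_error(build_confusion(known, rep("z", 10L), c("a", "b")), "label")
  cm2 <- build_confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(unclass(cm2)[1L, 2L], 1L)
})

test_that("packaged study matrices have the published margins", {
  d5_lda <- published_confusion("D5S818", "lda")
  expect_true(all(rowSums(d5_lda) >= 9L & rowSums(d5_lda) <= 49L))
  expect_equal(sum(d5_lda), 185L)
  d18_pca <- published_confusion("D18S51", "pca")
  expect_equal(sum(d18_pca), 104L)
  expect_true(all(rowSums(d18_pca) >= 14L & rowSums(d18_pca) <= 20L))
  d5_pca <- published_confusion("D5S818", "pca")
  expect_true(all(rowSums(d5_pca) >= 12L & rowSums(d5_pca) <= 67L))
  # genotype labels sort lexicographically by (allele_a, allele_b)
  expect_equal(rownames(d5_lda),
               vapply(str_panel("D5S818"), format, character(1L)))
})

test_that("confusion matrices round-trip through TSV", {
  cm <- rand_cm(c("(11,11)", "(11,12)", "(12,12)"), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(cm, path)
  expect_equal(read_confusion_tsv(path), cm)
})

test_that("overall and subset accuracies reproduce the published rates", {
  d5_lda <- published_confusion("D5S818", "lda")
  expect_equal(accuracy(d5_lda), 109 / 185)
  expect_equal(round(100 * accuracy(d5_lda), 2L), 58.92)
  homo <- c("(11,11)", "(12,12)", "(13,13)")
  het <- setdiff(rownames(d5_lda), homo)
  expect_equal(round(100 * subset_accuracy(d5_lda, homo, "micro"), 2L), 65.08)
  expect_equal(round(100 * subset_accuracy(d5_lda, het, "micro"), 2L), 55.74)
  d5_pca <- published_confusion("D5S818", "pca")
  expect_equal(round(100 * subset_accuracy(d5_pca, homo, "macro"), 2L), 39.58)
  expect_equal(round(100 * subset_accuracy(d5_pca, het, "macro"), 2L), 20.18)
  expect_equal(accuracy(published_confusion("D18S51", "lda")), 46 / 102)
  # subset = all rows reduces to overall accuracy
  expect_equal(subset_accuracy(d5_lda, rownames(d5_lda), "micro"),
               accuracy(d5_lda))
  expect_error(subset_accuracy(d5_lda, character(0L)))
  expect_error(subset_accuracy(d5_lda, "(9,9)"), "unknown label")
})

test_that("count-weighted micro subset accuracies average to the overall rate", {
  for (seed in 1:5) {
    cm <- rand_cm(sprintf("(%d,%d)", 11:15, 12:16), seed)
    split <- list(rownames(cm)[1:2], rownames(cm)[3:5])
    w <- vapply(split, function(s) sum(unclass(cm)[s, ]), numeric(1L))
    micro <- vapply(split, function(s) subset_accuracy(cm, s, "micro"),
                    numeric(1L))
    expect_equal(sum(w * micro) / sum(w), accuracy(cm))
  }
})

test_that("per-class recall handles published values, identities and zero rows", {
  d18_pca <- published_confusion("D18S51", "pca")
  rec <- per_class_recall(d18_pca)
  expect_equal(rec[["(12,16)"]], 8 / 14)
  expect_equal(round(100 * rec[["(12,16)"]], 2L), 57.14)
  eye4 <- diag(3L) * 4L
  dimnames(eye4) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(per_class_recall(as_confusion(eye4))), rep(1, 3L))
  m <- matrix(c(1L, 1L, 1L, 1L), 2L, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(per_class_recall(as_confusion(m))), c(0.5, 0.5))
  z <- matrix(c(2L, 1L, 0L, 0L), 2L, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(per_class_recall(as_confusion(z))[["b"]]))
})

test_that("near-miss predicate and rate follow the one-repeat-off rule", {
  expect_true(near_genotypes("(12,14)", "(12,15)"))
  expect_true(near_genotypes("(12,14)", "(13,14)"))
  expect_false(near_genotypes("(12,14)", "(13,16)"))
  expect_false(near_genotypes("(12,14)", "(12,16)"))
  expect_false(near_genotypes("(12,14)", "(12,14)"))
  expect_true(near_genotypes("(12,12)", "(12,13)"))
  # symmetry over the study panels
  panel <- vapply(c(str_panel("D5S818"), str_panel("D18S51")), format,
                  character(1L))
  for (a in panel) for (b in panel) {
    expect_identical(near_genotypes(a, b), near_genotypes(b, a))
  }
  d18_pca <- published_confusion("D18S51", "pca")
  expect_equal(near_miss_rate(d18_pca), 25 / 62)
  expect_equal(round(100 * near_miss_rate(d18_pca), 2L), 40.32)
  eye <- as_confusion(diag(2L) |>
                        `dimnames<-`(list(c("(11,11)", "(12,12)"),
                                          c("(11,11)", "(12,12)"))))
  expect_true(is.na(near_miss_rate(eye)))
})

test_that("geno-group collapsing conserves totals and never lowers accuracy", {
  d5 <- published_confusion("D5S818", "lda")
  schemes5 <- str_geno_group_schemes("D5S818")
  expect_length(schemes5, 6L)
  d18 <- published_confusion("D18S51", "pca")
  schemes18 <- str_geno_group_schemes("D18S51")
  expect_length(schemes18, 5L)
  for (sc in schemes5) {
    g <- collapse_confusion(d5, sc)
    expect_identical(sum(g), sum(d5))
    expect_gte(accuracy(g), accuracy(d5))
  }
  for (sc in schemes18) {
    g <- collapse_confusion(d18, sc)
    expect_identical(sum(g), sum(d18))
    expect_gte(accuracy(g), accuracy(d18))
  }
  # property over random matrices
  labs5 <- rownames(d5)
  for (seed in 1:10) {
    cm <- rand_cm(labs5, seed)
    for (sc in schemes5) {
      g <- collapse_confusion(cm, sc)
      expect_identical(sum(g), sum(cm))
      expect_gte(accuracy(g), accuracy(cm))
    }
  }
})

test_that("collapsing the published LDA matrix by its best grouping gives 147/185", {
  d5 <- published_confusion("D5S818", "lda")
  g <- collapse_confusion(d5, str_geno_group_schemes("D5S818")$A)
  expect_identical(sum(g), 185L)
  expect_equal(accuracy(g), 147 / 185)
})

test_that("identity and single-group schemes are collapse fixed points", {
  d5 <- published_confusion("D5S818", "lda")
  idm <- collapse_confusion(d5, identity_scheme(rownames(d5)))
  expect_equal(unclass(idm), unclass(d5), ignore_attr = TRUE)
  expect_equal(accuracy(idm), accuracy(d5))
  one <- geno_group_scheme("one", list(All = rownames(d5)))
  cm1 <- collapse_confusion(d5, one)
  expect_equal(dim(cm1), c(1L, 1L))
  expect_equal(accuracy(cm1), 1.0)
  # unmapped labels error
  partial <- geno_group_scheme("p", list(G = rownames(d5)[1:3]))
  expect_error(collapse_confusion(d5, partial), "does not map")
  expect_error(geno_group_scheme("dup", list(a = "(1,1)", b = "(1,1)")),
               "disjoint")
})

test_that("chance rate is one over the class count", {
  expect_equal(chance_rate(7), 1 / 7)
  expect_equal(round(100 * chance_rate(7), 2L), 14.29)
  expect_equal(chance_rate(1), 1.0)
  expect_equal(chance_rate(6), 1 / 6)
  expect_error(chance_rate(0), ">= 1")
})

test_that("grouping comparison supports collapse and retrain protocols", {
  feats <- simulate_features(recovery_config(), seed = 9, n_unknowns = 10L)
  std <- feats$role == "standard"
  x_tr <- feature_matrix(feats[std, ]); y_tr <- feats$genotype[std]
  x_te <- feature_matrix(feats[!std, ]); y_te <- feats$genotype[!std]
  schemes <- str_geno_group_schemes("D5S818")[c("A", "F")]
  res <- evaluate_grouping_options(x_tr, y_tr, x_te, y_te, schemes,
                                   classifier = "lda")
  expect_equal(nrow(res), 4L)
  expect_setequal(res$protocol, c("collapse", "retrain"))
  # ungrouped baseline
  base <- fit_lda(x_tr, y_tr)
  base_acc <- mean(predict_lda(base, x_te)$label == y_te)
  expect_true(all(res$accuracy[res$protocol == "collapse"] >= base_acc))
  # identity scheme under collapse reproduces the ungrouped accuracy exactly
  idres <- evaluate_grouping_options(x_tr, y_tr, x_te, y_te,
                                     list(id = identity_scheme(unique(y_tr))),
                                     classifier = "lda", protocols = "collapse")
  expect_equal(idres$accuracy, base_acc)
  # retrain returns group-level confusion matrices of the right shape
  cms <- attr(res, "confusions")
  expect_equal(dim(cms[["A.retrain"]]), c(3L, 3L))
  expect_equal(rownames(cms[["A.retrain"]]), names(schemes$A$groups))
})
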