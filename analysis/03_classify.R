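#!/usr/bin/env Rscript
# Train both classifiers on the standards and predict the unknowns.
# LDA works on the fixed-length feature vectors; PCA cluster typing works on
# normalized derivative curves. Models are serialized to JSON so unknowns can
# be typed later without re-running the standards.

library(meltSTR)

config <- hrm_config()

for (locus in c("D5S818", "D18S51")) {
  feats <- read_feature_table(file.path("results",
                                        sprintf("features_%s.tsv", locus)))
  std <- feats$role == "standard"

  ## LDA on feature vectors
  model <- fit_lda(feature_matrix(feats[std, ]), feats$genotype[std],
                   ridge = config$lda$ridge)
  write_lda_model(model, file.path("results", sprintf("lda_%s.json", locus)))
  pred <- predict_lda(model, feature_matrix(feats[!std, ]))

  ## PCA typing on normalized curves
  curves <- read_melt_table(file.path("results", sprintf("melt_%s.csv", locus)),
                            locus = locus)
  ids <- vapply(curves, `[[`, character(1L), "sample_id")
  norm <- lapply(curves, function(cu) normalize_curve(
    compute_derivative(cu, config$derivative$window, config$derivative$degree),
    melt_window = config$peaks$melt_window))
  std_ids <- feats$sample_id[std]
  unk_ids <- feats$sample_id[!std]
  pca <- fit_pca_typing(norm[match(std_ids, ids)], feats$genotype[std],
                        m = config$pca$m,
                        typing_quantile = config$pca$typing_quantile,
                        pooled = config$pca$pooled)
  write_pca_model(pca, file.path("results", sprintf("pca_%s.json", locus)))
  typed <- lapply(norm[match(unk_ids, ids)], function(cu) type_unknown(pca, cu))

  out <- data.frame(sample_id = unk_ids,
                    known = feats$genotype[!std],
                    lda_predicted = pred$label,
                    lda_posterior = apply(pred$posterior, 1L, max),
                    pca_predicted = vapply(typed, `[[`, character(1L), "label"),
                    pca_posterior = vapply(typed, function(r) max(r$posterior),
                                           numeric(1L)),
                    pca_mahalanobis = vapply(typed, `[[`, numeric(1L),
                                             "mahalanobis"))
  write.table(out, file.path("results", sprintf("predictions_%s.tsv", locus)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s: LDA accuracy %.3f, PCA accuracy %.3f (%d unclassified)\n",
              locus, mean(out$lda_predicted == out$known),
              mean(out$pca_predicted == out$known),
              sum(out$pca_predicted == "UNCLASSIFIED")))
}
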