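#!/usr/bin/env Rscript
# Evaluate the predictions: per-locus confusion matrices with overall,
# homozygous/heterozygous and per-genotype rates, near-miss analysis, and the
# published geno-group schemes compared under both protocols (post-hoc
# collapse vs retrain on group labels).

library(meltSTR)

for (locus in c("D5S818", "D18S51")) {
  pred <- read.delim(file.path("results", sprintf("predictions_%s.tsv", locus)),
                     check.names = FALSE)
  panel <- vapply(str_panel(locus), format, character(1L))
  for (method in c("lda", "pca")) {
    p <- pred[[paste0(method, "_predicted")]]
    keep <- p != "UNCLASSIFIED"
    cm <- build_confusion(pred$known[keep], p[keep], panel)
    write_confusion_tsv(cm, file.path("results",
                                      sprintf("confusion_%s_%s.tsv", locus, method)))
    homo <- panel[vapply(panel, function(l) is_homozygous(parse_genotype(l)),
                         logical(1L))]
    nm <- near_miss_rate(cm)
    cat(sprintf("%s/%s: overall %.2f%%, chance %.2f%%%s%s\n",
                locus, toupper(method), 100 * accuracy(cm),
                100 * chance_rate(length(panel)),
                if (length(homo) > 0)
                  sprintf(", homozygous (micro) %.2f%%",
                          100 * subset_accuracy(cm, homo, "micro")) else "",
                if (!is.na(nm)) sprintf(", near-miss %.2f%%", 100 * nm) else ""))
  }

  # geno-group options under both protocols, LDA features
  feats <- read_feature_table(file.path("results",
                                        sprintf("features_%s.tsv", locus)))
  std <- feats$role == "standard"
  res <- evaluate_grouping_options(
    feature_matrix(feats[std, ]), feats$genotype[std],
    feature_matrix(feats[!std, ]), feats$genotype[!std],
    str_geno_group_schemes(locus), classifier = "lda")
  write.table(res, file.path("results", sprintf("geno_groups_%s.tsv", locus)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  best <- res[which.max(res$accuracy), ]
  cat(sprintf("%s geno-groups: best option %s (%s protocol) at %.2f%%\n",
              locus, best$scheme, best$protocol, 100 * best$accuracy))
}
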