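#!/usr/bin/env Rscript
# Extract fixed-length peak/shoulder feature vectors from the simulated melt
# curves: 3 observations per D5S818 sample, 4 per D18S51 sample, padding at
# 64.95 degC where a curve shows fewer peaks than the target count.

library(meltSTR)

config <- hrm_config()

for (locus in c("D5S818", "D18S51")) {
  curves <- read_melt_table(file.path("results", sprintf("melt_%s.csv", locus)),
                            locus = locus)
  metadata <- read_sample_metadata(file.path("results",
                                             sprintf("samples_%s.tsv", locus)))
  feats <- curves_to_features(curves, k = config$features$k[[locus]],
                              metadata = metadata,
                              window = config$derivative$window,
                              degree = config$derivative$degree,
                              cfg = config_peaks(config))
  write_feature_table(feats, file.path("results",
                                       sprintf("features_%s.tsv", locus)))
  kinds <- table(unlist(strsplit(feats$kinds, ",")))
  cat(sprintf("%s: %d samples featurized (%s)\n", locus, nrow(feats),
              paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", ")))
}
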