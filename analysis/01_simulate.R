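#!/usr/bin/env Rscript
# Simulate HRM study datasets for both STR loci and write them to disk in the
# interchange formats (wide melt-curve CSV + sample-metadata TSV).
#
# Study layout mirrors the published design: 8 standards per genotype
# (7 D5S818 genotypes -> 56 standards; the D18S51 panel has 6) plus 20
# unknowns per genotype for prediction.

library(meltSTR)

seed <- 1L
dir.create("results", showWarnings = FALSE)
cfg <- config_simulation(hrm_config())

for (locus in c("D5S818", "D18S51")) {
  spec <- str_locus(locus)
  ds <- simulate_dataset(spec, n_standards = 8L, n_unknowns = 20L,
                         cfg = cfg, seed = seed)
  write_melt_table(ds$curves, file.path("results", sprintf("melt_%s.csv", locus)))
  write_sample_metadata(ds$metadata,
                        file.path("results", sprintf("samples_%s.tsv", locus)))
  cat(sprintf("%s: %d standards, %d unknowns written\n", locus,
              sum(ds$metadata$role == "standard"),
              sum(ds$metadata$role == "unknown")))
}
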