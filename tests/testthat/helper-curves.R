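# Analytic melt-curve builders used across tests. A logistic transition at Tm
# with slope s releases amplitude A of fluorescence as T rises through Tm.
logistic_curve <- function(tms, amps, slope = 0.3, grid = canonical_grid(),
                           baseline = 0, id = "sim") {
  f <- rep(baseline, length(grid))
  for (i in seq_along(tms)) {
    f <- f + amps[i] / (1 + exp((grid - tms[i]) / slope))
  }
  melt_curve(id, "TEST", grid, f)
}

# Low-noise D5S818 study regime used by the parameter-recovery checks:
# one-repeat Tm spacing ~0.26 degC, per-sample Tm jitter 0.05 degC, reading
# noise 0.2% of amplitude.
recovery_config <- function(noise_scale = 1) {
  simulation_config(tm_coeffs = c(73.0, 41.0, 1700.0),
                    noise_sd = 2 * noise_scale,
                    tm_jitter_sd = 0.05 * noise_scale)
}

# Well-separated regime (~0.78 degC per repeat) for cluster-typing checks.
separated_config <- function() {
  simulation_config(tm_coeffs = c(95.0, 41.0, 5200.0),
                    noise_sd = 2, tm_jitter_sd = 0.05)
}

simulate_features <- function(cfg, seed, n_standards = 8L, n_unknowns = 20L,
                              locus = "D5S818", k = 3L) {
  spec <- str_locus(locus)
  ds <- simulate_dataset(spec, n_standards = n_standards,
                         n_unknowns = n_unknowns, cfg = cfg, seed = seed)
  feats <- suppressWarnings(curves_to_features(ds$curves, k = k,
                                               metadata = ds$metadata))
  feats
}
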