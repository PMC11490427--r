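# Default analysis configuration: every tunable threshold of the pipeline.
derivative:
  window: 11        # Savitzky-Golay window (odd number of midpoint-grid points)
  degree: 3         # local polynomial degree
peaks:
  melt_window: [70.0, 90.0]   # degC interval searched for melting transitions
  prominence_frac: 0.05       # resolved-peak prominence threshold (fraction of max)
  terrace_frac: 0.15          # flank-flattening threshold for unresolved shoulders
features:
  k:
    D5S818: 3
    D18S51: 4
  pad_temperature: 64.95      # degC; native midpoint-grid point below all transitions
lda:
  priors: uniform
  ridge: 1.0e-6
pca:
  m: 2
  typing_quantile: 0.999
  pooled: true
simulation:
  tm_coeffs: [67.0, 41.0, 675.0]   # Tm = c0 + c1*gc - c2/length
  transition_slope: 0.3            # degC
  amplitude: 1000.0
  baseline: [100.0, -0.2]          # intercept, slope per degC
  heteroduplex:
    enabled: false
    delta_tm: 1.0
    weight: 0.3
  noise_sd: 2.0                    # fluorescence units
  tm_jitter_sd: 0.05               # degC
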