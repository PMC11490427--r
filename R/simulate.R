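#' Simulation configuration for synthetic melt curves
#'
#' The simulator models each amplicon species as a two-state logistic melting
#' transition. For one sample of genotype `(a, b)`:
#' \deqn{F(T) = b_0 + b_1 (T - 60) + A \sum_i w_i\,
#'   \sigma\!\big((Tm_i + J - T)/s\big) + \varepsilon(T),}
#' where the sum runs over the allele species (heterozygotes contribute two
#' species of weight 1; homozygotes a single species of weight 2, plus an
#' optional heteroduplex species melting `delta_het` degC below the lower
#' allele), `J ~ N(0, tm_jitter_sd^2)` is a per-sample run-to-run shift drawn
#' once, and `epsilon` is iid per-reading Gaussian noise. The per-allele
#' melting temperature follows the empirical GC/length law
#' `Tm = c0 + c1 * gc - c2 / amplicon_length` (see [allele_tm()]), whose
#' default coefficients put one repeat unit (4 bp) at roughly a 0.1 degC Tm
#' shift — deliberately small, reproducing the central difficulty of closely
#' related STR genotypes whose curves nearly overlap.
#'
#' @param tm_coeffs Numeric `c(c0, c1, c2)`: offset (degC), GC coefficient
#'   (degC per GC fraction), length coefficient (degC * bp).
#' @param transition_slope Logistic slope parameter `s` (degC) of each
#'   melting transition; ~4 s is the transition width.
#' @param amplitude Fluorescence released per unit species weight.
#' @param baseline Numeric `c(intercept, slope)` of the linear background
#'   (slope in fluorescence units per degC; non-positive keeps noiseless
#'   curves non-increasing).
#' @param heteroduplex List `(enabled, delta_tm, weight)`: optional
#'   heteroduplex species for heterozygotes, melting `delta_tm` degC below
#'   the lower-allele homoduplex. Off by default.
#' @param noise_sd Per-reading fluorescence noise SD.
#' @param tm_jitter_sd Per-sample Tm jitter SD (degC).
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(tm_coeffs = c(c0 = 67.0, c1 = 41.0, c2 = 675.0),
                              transition_slope = 0.3,
                              amplitude = 1000,
                              baseline = c(intercept = 100, slope = -0.2),
                              heteroduplex = list(enabled = FALSE,
                                                  delta_tm = 1.0, weight = 0.3),
                              noise_sd = 2,
                              tm_jitter_sd = 0.05) {
  stopifnot(length(tm_coeffs) == 3L, transition_slope > 0, amplitude > 0,
            length(baseline) == 2L, noise_sd >= 0, tm_jitter_sd >= 0,
            heteroduplex$delta_tm >= 0, heteroduplex$weight > 0)
  structure(list(tm_coeffs = as.numeric(tm_coeffs),
                 transition_slope = transition_slope, amplitude = amplitude,
                 baseline = as.numeric(baseline), heteroduplex = heteroduplex,
                 noise_sd = noise_sd, tm_jitter_sd = tm_jitter_sd),
            class = "simulation_config")
}

#' Amplicon length of one allele
#'
#' `flank_length + motif_length * repeats` base pairs.
#'
#' @param spec A [locus_spec()].
#' @param repeats Repeat count, within the locus's allele range.
#' @return Length in bp.
#' @export
allele_amplicon_length <- function(spec, repeats) {
  stopifnot(inherits(spec, "locus_spec"))
  repeats <- as.integer(repeats)
  if (any(repeats < spec$allele_range[1L]) || any(repeats > spec$allele_range[2L])) {
    stop(sprintf("repeat count outside %s allele range [%d, %d]", spec$name,
                 spec$allele_range[1L], spec$allele_range[2L]), call. = FALSE)
  }
  spec$flank_length + spec$motif_length * repeats
}

#' Melting temperature of one allele's amplicon
#'
#' Empirical GC/length law `Tm = c0 + c1 * gc_fraction - c2 / length`
#' (Marmur-Schildkraut-shaped): Tm rises with GC content and, for `c2 > 0`,
#' increases strictly with amplicon length, so longer alleles melt later.
#'
#' @param spec A [locus_spec()].
#' @param repeats Repeat count.
#' @param coeffs Numeric `c(c0, c1, c2)`; defaults from [simulation_config()].
#' @return Tm in degC.
#' @examples
#' allele_tm(str_locus("D5S818"), 11)  # 67 + 41*0.38 - 675/163 = 78.439
#' @export
allele_tm <- function(spec, repeats, coeffs = simulation_config()$tm_coeffs) {
  len <- allele_amplicon_length(spec, repeats)
  coeffs[1L] + coeffs[2L] * spec$gc_fraction - coeffs[3L] / len
}

#' Simulate one melt curve
#'
#' @param spec A [locus_spec()].
#' @param geno A [genotype()].
#' @param cfg A [simulation_config()].
#' @param sample_id Sample identifier.
#' @param role `"standard"` or `"unknown"`.
#' @param temperatures Acquisition grid; canonical 60-95/0.1 by default.
#' @return A [melt_curve()] with attributes `genotype` (label) and `role`.
#' @export
simulate_curve <- function(spec, geno, cfg = simulation_config(),
                           sample_id = "sim", role = "unknown",
                           temperatures = canonical_grid()) {
  stopifnot(inherits(spec, "locus_spec"), inherits(geno, "genotype"),
            inherits(cfg, "simulation_config"))
  if (is_homozygous(geno)) {
    tms <- allele_tm(spec, geno[[1L]], cfg$tm_coeffs)
    w <- 2
  } else {
    tms <- c(allele_tm(spec, geno[[1L]], cfg$tm_coeffs),
             allele_tm(spec, geno[[2L]], cfg$tm_coeffs))
    w <- c(1, 1)
    if (isTRUE(cfg$heteroduplex$enabled)) {
      tms <- c(tms, min(tms) - cfg$heteroduplex$delta_tm)
      w <- c(w, cfg$heteroduplex$weight)
    }
  }
  jitter <- stats::rnorm(1L, 0, cfg$tm_jitter_sd)
  f <- cfg$baseline[1L] + cfg$baseline[2L] * (temperatures - 60)
  for (i in seq_along(tms)) {
    f <- f + cfg$amplitude * w[i] /
      (1 + exp(-(tms[i] + jitter - temperatures) / cfg$transition_slope))
  }
  f <- f + stats::rnorm(length(temperatures), 0, cfg$noise_sd)
  cu <- melt_curve(sample_id, spec$name, temperatures, f)
  attr(cu, "genotype") <- format(geno)
  attr(cu, "role") <- role
  cu
}

#' Simulate a full study dataset for one locus
#'
#' Generates `n_standards` training samples and `n_unknowns` test samples
#' per genotype. Each sample draws from its own RNG substream derived from
#' `(seed, sample index)`, so datasets are reproducible and independent of
#' generation order.
#'
#' @param spec A [locus_spec()].
#' @param panel List of [genotype()] objects; defaults to the built-in study
#'   panel for the locus.
#' @param n_standards,n_unknowns Samples per genotype (the study design used
#'   7-10 standards per genotype).
#' @param cfg A [simulation_config()].
#' @param seed Integer master seed.
#' @return List with `curves` (list of [melt_curve()]) and `metadata` (data
#'   frame: `sample_id`, `locus`, `genotype`, `role`).
#' @export
simulate_dataset <- function(spec, panel = NULL, n_standards = 8L,
                             n_unknowns = 20L, cfg = simulation_config(),
                             seed = 1L) {
  stopifnot(inherits(spec, "locus_spec"))
  if (is.null(panel)) panel <- str_panel(spec$name)
  stopifnot(length(panel) > 0L)
  curves <- list()
  meta <- list()
  idx <- 0L
  for (gi in seq_along(panel)) {
    geno <- panel[[gi]]
    for (role in c("standard", "unknown")) {
      n_role <- if (role == "standard") n_standards else n_unknowns
      for (r in seq_len(n_role)) {
        idx <- idx + 1L
        # no commas: ids double as CSV column headers
        sid <- sprintf("%s_%d-%d_%s%02d", spec$name, geno[[1L]], geno[[2L]],
                       substr(role, 1L, 3L), r)
        # per-sample substream: order-independent reproducibility
        sub_seed <- (as.integer(seed) %% 65536L) * 32749L + idx * 7919L
        set.seed(sub_seed %% 2147483647L)
        curves[[idx]] <- simulate_curve(spec, geno, cfg, sample_id = sid,
                                        role = role)
        meta[[idx]] <- data.frame(sample_id = sid, locus = spec$name,
                                  genotype = format(geno), role = role,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = curves, metadata = do.call(rbind, meta))
}
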