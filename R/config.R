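#' Analysis configuration
#'
#' All pipeline thresholds live in one YAML file; `hrm_config()` loads the
#' packaged defaults and merges any user overrides on top (shallow-recursive
#' merge: user values win, missing keys fall back to defaults).
#'
#' @param path Optional path to a user YAML file.
#' @return Nested named list of configuration values.
#' @export
hrm_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "meltSTR"))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  merge_lists(defaults, yaml::read_yaml(path))
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Simulation config from a configuration list
#'
#' @param config List from [hrm_config()].
#' @return A [simulation_config()].
#' @export
config_simulation <- function(config = hrm_config()) {
  s <- config$simulation
  simulation_config(
    tm_coeffs = as.numeric(s$tm_coeffs),
    transition_slope = s$transition_slope,
    amplitude = s$amplitude,
    baseline = as.numeric(s$baseline),
    heteroduplex = s$heteroduplex,
    noise_sd = s$noise_sd,
    tm_jitter_sd = s$tm_jitter_sd
  )
}

#' Peak config from a configuration list
#'
#' @param config List from [hrm_config()].
#' @return A [peak_config()].
#' @export
config_peaks <- function(config = hrm_config()) {
  p <- config$peaks
  peak_config(melt_window = as.numeric(p$melt_window),
              prominence_frac = p$prominence_frac,
              terrace_frac = p$terrace_frac)
}
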