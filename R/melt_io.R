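#' Melt curves
#'
#' A melt curve is the raw HRM trace for one sample at one locus: fluorescence
#' recorded while the amplicon is heated over a strictly increasing
#' temperature grid. The canonical acquisition grid is 60.0-95.0 degC in
#' 0.1 degC steps (351 points); other strictly increasing grids are accepted
#' with a warning, since the derivative stage needs only monotonicity.
#'
#' @param sample_id Sample identifier.
#' @param locus Locus identifier.
#' @param temperatures Strictly increasing numeric vector (degC), length >= 10.
#' @param fluorescence Numeric vector of the same length (arbitrary units).
#' @return A `"melt_curve"` list.
#' @export
melt_curve <- function(sample_id, locus, temperatures, fluorescence) {
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) != length(fluorescence)) {
    stop("temperatures and fluorescence must have equal length", call. = FALSE)
  }
  if (length(temperatures) < 10L) {
    stop("a melt curve needs at least 10 readings", call. = FALSE)
  }
  if (any(!is.finite(temperatures)) || any(diff(temperatures) <= 0)) {
    stop("temperatures must be finite and strictly increasing", call. = FALSE)
  }
  if (!is_canonical_grid(temperatures)) {
    warning(sprintf("sample '%s': temperature grid is not the canonical 60-95 degC / 0.1 degC ramp",
                    sample_id), call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), locus = as.character(locus),
         temperatures = temperatures, fluorescence = fluorescence),
    class = "melt_curve"
  )
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve %s @ %s: %d points, %.2f-%.2f degC>\n",
              x$sample_id, x$locus, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' The canonical 60-95 degC / 0.1 degC melt ramp
#' @return Numeric vector of 351 temperatures.
#' @export
canonical_grid <- function() seq(60, 95, by = 0.1)

is_canonical_grid <- function(temps) {
  g <- canonical_grid()
  length(temps) == length(g) && all(abs(temps - g) < 1e-6)
}

#' Read and write wide-format melt-curve tables
#'
#' The interchange format is a wide CSV: a `Temperature` column followed by
#' one fluorescence column per sample, with the sample id as column header.
#' All curves in one file share the temperature grid.
#'
#' @param path File path.
#' @param locus Locus identifier attached to every curve read.
#' @return `read_melt_table()` returns a list of [melt_curve()] objects.
#' @export
read_melt_table <- function(path, locus = "unknown") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) < 2L) stop("melt table has no data rows", call. = FALSE)
  if (length(unique(nf)) != 1L) {
    stop("ragged melt table: rows have differing field counts", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("melt table needs a Temperature column plus >= 1 sample column",
                          call. = FALSE)
  if (!identical(tolower(names(df)[1L]), "temperature")) {
    stop("first column must be 'Temperature'", call. = FALSE)
  }
  temps <- as.numeric(df[[1L]])
  if (any(is.na(temps)) || any(vapply(df[-1L], function(col) any(is.na(as.numeric(col))), logical(1L)))) {
    stop("melt table body must be numeric", call. = FALSE)
  }
  if (any(diff(temps) <= 0)) {
    stop("temperature column must be strictly increasing", call. = FALSE)
  }
  lapply(names(df)[-1L], function(id) {
    melt_curve(id, locus, temps, as.numeric(df[[id]]))
  })
}

#' @rdname read_melt_table
#' @param curves List of [melt_curve()] objects sharing one temperature grid.
#' @details Temperatures are written with 2 decimals and fluorescence with 6
#'   significant digits, so a write/read round trip preserves values to that
#'   precision.
#' @export
write_melt_table <- function(curves, path) {
  if (length(curves) == 0L) stop("no curves to write", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1L), "melt_curve")))
  temps <- curves[[1L]]$temperatures
  for (cu in curves[-1L]) {
    if (length(cu$temperatures) != length(temps) ||
        any(abs(cu$temperatures - temps) > 1e-9)) {
      stop("all curves must share an identical temperature grid", call. = FALSE)
    }
  }
  df <- data.frame(Temperature = sprintf("%.2f", temps), check.names = FALSE)
  for (cu in curves) {
    df[[cu$sample_id]] <- formatC(signif(cu$fluorescence, 6L), format = "g",
                                  digits = 6L)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `locus`, `allele_a`,
#' `allele_b`, `role`. `role` is `"standard"` (training sample of known
#' genotype) or `"unknown"`. Standards must carry a genotype; genotypes are
#' canonicalized on read (`allele_a <= allele_b`). Unknown samples of known
#' truth (simulated data) may also carry alleles; truly blind unknowns use
#' `NA`.
#'
#' @param path File path.
#' @return A data frame with columns `sample_id`, `locus`, `genotype`
#'   (canonical `"(a,b)"` label or `NA`) and `role`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "locus", "allele_a", "allele_b", "role")
  if (!all(need %in% names(df))) {
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("standard", "unknown"))
  if (length(bad_role) > 0L) {
    stop(sprintf("unknown role token(s): %s", paste(bad_role, collapse = ", ")),
         call. = FALSE)
  }
  geno <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    a <- df$allele_a[i]; b <- df$allele_b[i]
    if (is.na(a) || is.na(b)) {
      if (df$role[i] == "standard") {
        stop(sprintf("standard sample '%s' lacks a known genotype", df$sample_id[i]),
             call. = FALSE)
      }
      geno[i] <- NA_character_
    } else {
      geno[i] <- format(genotype(a, b))
    }
  }
  data.frame(sample_id = as.character(df$sample_id),
             locus = as.character(df$locus),
             genotype = geno, role = df$role,
             stringsAsFactors = FALSE)
}

#' @rdname read_sample_metadata
#' @param metadata Data frame as returned by [read_sample_metadata()].
#' @export
write_sample_metadata <- function(metadata, path) {
  alleles <- t(vapply(metadata$genotype, function(g) {
    if (is.na(g)) c(NA_integer_, NA_integer_) else unclass(parse_genotype(g))
  }, integer(2L)))
  out <- data.frame(sample_id = metadata$sample_id, locus = metadata$locus,
                    allele_a = alleles[, 1L], allele_b = alleles[, 2L],
                    role = metadata$role)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write feature tables
#'
#' Feature tables are TSV: `sample_id`, `locus`, `genotype` (or NA), then
#' interleaved `T1,h1,...,Tk,hk` columns and a `kinds` column recording each
#' observation's type (`primary`, `shoulder_resolved`, `shoulder_unresolved`,
#' `pad`) as a comma-joined string.
#'
#' @param features Feature data frame as built by [curves_to_features()].
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
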