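#' STR locus specifications
#'
#' A `locus_spec` bundles what the simulator and feature extractor need to
#' know about one STR locus: the repeat motif length, the length of the
#' non-repeat (flanking) part of the amplicon, an aggregate GC fraction, the
#' PCR primer pair, and the supported allele range.
#'
#' @param name Locus identifier, e.g. `"D5S818"`.
#' @param motif_length Base pairs per repeat unit (>= 1); 4 for the
#'   tetranucleotide loci shipped with the package.
#' @param flank_length Base pairs of amplicon outside the repeat tract.
#' @param gc_fraction Amplicon GC fraction in `[0, 1]`.
#' @param forward_primer,reverse_primer Uppercase ACGT primer sequences.
#' @param allele_range Length-2 integer vector, `c(min, max)` repeat counts.
#' @return A `"locus_spec"` list.
#' @seealso [str_locus()] for the built-in D5S818 and D18S51 definitions.
#' @export
locus_spec <- function(name, motif_length, flank_length, gc_fraction,
                       forward_primer, reverse_primer, allele_range) {
  stopifnot(is.character(name), nzchar(name))
  motif_length <- as.integer(motif_length)
  flank_length <- as.integer(flank_length)
  if (motif_length < 1L) stop("motif_length must be >= 1", call. = FALSE)
  if (flank_length < 0L) stop("flank_length must be >= 0", call. = FALSE)
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (p in c(forward_primer, reverse_primer)) {
    if (!nzchar(p) || grepl("[^ACGT]", p)) {
      stop("primers must be non-empty uppercase ACGT strings", call. = FALSE)
    }
  }
  allele_range <- as.integer(allele_range)
  stopifnot(length(allele_range) == 2L, allele_range[1L] <= allele_range[2L])
  structure(
    list(name = name, motif_length = motif_length,
         flank_length = flank_length, gc_fraction = gc_fraction,
         forward_primer = forward_primer, reverse_primer = reverse_primer,
         allele_range = allele_range),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec %s: %d bp motif, %d bp flank, GC %.2f, alleles %d-%d>\n",
              x$name, x$motif_length, x$flank_length, x$gc_fraction,
              x$allele_range[1L], x$allele_range[2L]))
  invisible(x)
}

# Flank lengths and GC fractions are simulator calibration choices (the
# vignette documents them); primer sequences are the published assay primers.
.builtin_loci <- function() {
  list(
    D5S818 = locus_spec(
      name = "D5S818", motif_length = 4L, flank_length = 119L,
      gc_fraction = 0.38,
      forward_primer = "GGGTGATTTTCCTCTTTGGT",
      reverse_primer = "AACATTTGTATCTTTATCTGTATCCTTATTTAT",
      allele_range = c(7L, 16L)
    ),
    D18S51 = locus_spec(
      name = "D18S51", motif_length = 4L, flank_length = 131L,
      gc_fraction = 0.365,
      forward_primer = "CAAACCCGACTACCAGCAAC",
      reverse_primer = "GAGCCATGTTCATGCCACTG",
      allele_range = c(9L, 26L)
    )
  )
}

#' Built-in locus definitions
#'
#' Returns the packaged [locus_spec()] for one of the two STR loci the
#' package ships with (`"D5S818"`, `"D18S51"`).
#'
#' @param name Locus name.
#' @return A `locus_spec`.
#' @examples
#' str_locus("D5S818")$forward_primer
#' @export
str_locus <- function(name = c("D5S818", "D18S51")) {
  name <- match.arg(name)
  .builtin_loci()[[name]]
}

#' Genotype panels used in the D5S818 / D18S51 study design
#'
#' The seven closely related D5S818 genotypes and six closely related D18S51
#' genotypes whose melt curves the classifiers are trained to distinguish.
#'
#' @param locus Locus name.
#' @return A list of [genotype()] objects, in lexicographic label order.
#' @export
str_panel <- function(locus = c("D5S818", "D18S51")) {
  locus <- match.arg(locus)
  pairs <- switch(locus,
    D5S818 = list(c(10, 11), c(11, 11), c(11, 12), c(11, 13),
                  c(12, 12), c(12, 13), c(13, 13)),
    D18S51 = list(c(12, 14), c(12, 15), c(12, 16), c(13, 14),
                  c(13, 16), c(14, 15))
  )
  lapply(pairs, function(p) genotype(p[1L], p[2L]))
}
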