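#' STR genotypes
#'
#' A genotype at an STR locus is an unordered pair of allele repeat counts.
#' It is stored canonically with `allele_a <= allele_b`, and rendered as
#' `"(a,b)"`, the label convention used throughout confusion matrices and
#' geno-group schemes. A genotype is homozygous iff both alleles are equal.
#'
#' @param allele_a,allele_b Integer repeat counts (>= 1). Order is irrelevant;
#'   the constructor canonicalizes.
#' @return `genotype()` returns a `"genotype"` object (a named integer pair).
#' @examples
#' g <- genotype(13, 11)
#' format(g)            # "(11,13)"
#' is_homozygous(g)     # FALSE
#' @export
genotype <- function(allele_a, allele_b) {
  a <- as.integer(allele_a)
  b <- as.integer(allele_b)
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b)) {
    stop("alleles must be single non-missing integers", call. = FALSE)
  }
  if (a < 1L || b < 1L) {
    stop("allele repeat counts must be >= 1", call. = FALSE)
  }
  g <- c(allele_a = min(a, b), allele_b = max(a, b))
  class(g) <- "genotype"
  g
}

#' @rdname genotype
#' @param g A `genotype` object.
#' @export
is_homozygous <- function(g) {
  stopifnot(inherits(g, "genotype"))
  unname(g[1L] == g[2L])
}

#' @export
format.genotype <- function(x, ...) {
  sprintf("(%d,%d)", x[[1L]], x[[2L]])
}

#' @export
print.genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a genotype label
#'
#' Inverse of `format.genotype()`: parses strings such as `"(11,13)"` (or
#' bare `"11,13"`) into canonical [genotype()] objects.
#'
#' @param label Character scalar or vector of labels.
#' @return A `genotype` for a single label, else a list of genotypes.
#' @export
parse_genotype <- function(label) {
  parse1 <- function(s) {
    m <- regmatches(s, regexec("^\\(?\\s*(\\d+)\\s*,\\s*(\\d+)\\s*\\)?$", s))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse genotype label '%s'", s), call. = FALSE)
    }
    genotype(as.integer(m[2L]), as.integer(m[3L]))
  }
  if (length(label) == 1L) parse1(label) else lapply(label, parse1)
}

#' Near-miss predicate for a pair of genotypes
#'
#' Two distinct genotypes are a "near miss" when they share exactly one allele
#' value and the remaining two alleles differ by exactly one repeat unit, with
#' the shared allele chosen over both possible pairings. Near misses are the
#' dominant misclassification pattern for closely related STR genotypes, where
#' one allele melts indistinguishably and the other is off by a single repeat.
#'
#' @param g,p Genotypes (objects or labels). Symmetric in its arguments.
#' @return Logical scalar.
#' @examples
#' near_genotypes("(12,14)", "(12,15)")  # TRUE: share 12, 14 vs 15
#' near_genotypes("(12,14)", "(13,16)")  # FALSE: nothing shared
#' @export
near_genotypes <- function(g, p) {
  if (!inherits(g, "genotype")) g <- parse_genotype(g)
  if (!inherits(p, "genotype")) p <- parse_genotype(p)
  if (g[[1L]] == p[[1L]] && g[[2L]] == p[[2L]]) return(FALSE)
  # try both pairings of (g_a, g_b) against (p_a, p_b)
  pairings <- list(c(1L, 2L), c(2L, 1L))
  for (idx in pairings) {
    same <- c(g[[1L]] == p[[idx[1L]]], g[[2L]] == p[[idx[2L]]])
    diff1 <- c(abs(g[[1L]] - p[[idx[1L]]]) == 1L, abs(g[[2L]] - p[[idx[2L]]]) == 1L)
    if ((same[1L] && diff1[2L]) || (same[2L] && diff1[1L])) return(TRUE)
  }
  FALSE
}
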