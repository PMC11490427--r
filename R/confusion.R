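#' Confusion matrices
#'
#' The unit of all reported prediction statistics: a square count table with
#' rows indexed by known class and columns by predicted class, in a shared
#' label order (genotype labels sort lexicographically by `(allele_a,
#' allele_b)`, matching published tables).
#'
#' @param known,predicted Equal-length label vectors.
#' @param label_order Ordered label set; every known/predicted label must be
#'   a member. Defaults to the sorted union of the observed labels.
#' @return A `"confusion_matrix"`: an integer matrix with dimnames.
#' @export
build_confusion <- function(known, predicted, label_order = NULL) {
  known <- as.character(known)
  predicted <- as.character(predicted)
  stopifnot(length(known) == length(predicted), length(known) > 0L)
  if (is.null(label_order)) label_order <- sort(unique(c(known, predicted)))
  extra <- setdiff(unique(c(known, predicted)), label_order)
  if (length(extra) > 0L) {
    stop(sprintf("label(s) not in label_order: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  tab <- table(factor(known, levels = label_order),
               factor(predicted, levels = label_order))
  cm <- matrix(as.integer(tab), nrow = length(label_order),
               dimnames = list(known = label_order, predicted = label_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Construct a confusion matrix from a count table
#'
#' @param counts Square non-negative integer matrix with identical row and
#'   column label sets.
#' @rdname build_confusion
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (is.null(rownames(counts)) || !identical(rownames(counts), colnames(counts))) {
    stop("row and column labels must be present and identical", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("grand total must be positive", call. = FALSE)
  storage.mode(counts) <- "integer"
  names(dimnames(counts)) <- c("known", "predicted")
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("accuracy: %.4f (%d/%d)\n", accuracy(x),
              sum(diag(unclass(x))), sum(x)))
  invisible(x)
}

#' Read / write a confusion matrix as TSV
#'
#' Layout: first header cell `known`, then predicted labels; one row per
#' known label.
#'
#' @param path File path.
#' @export
read_confusion_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  colnames(m) <- colnames(df)
  as_confusion(m)
}

#' @rdname read_confusion_tsv
#' @param cm A `confusion_matrix`.
#' @export
write_confusion_tsv <- function(cm, path) {
  df <- data.frame(known = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Overall (micro) accuracy
#'
#' Fraction of samples on the diagonal: `trace / grand total`.
#'
#' @param cm A `confusion_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sum(diag(unclass(cm))) / sum(cm)
}

#' Accuracy over a subset of known classes
#'
#' Published HRM genotyping studies report homozygous/heterozygous accuracy
#' splits under both aggregations, so both are first-class:
#' `micro` pools counts (sum of subset diagonal over sum of subset row
#' totals); `macro` averages the per-row recalls of the subset.
#'
#' @param cm A `confusion_matrix`.
#' @param row_subset Known-class labels to restrict to (non-empty).
#' @param mode `"micro"` or `"macro"`.
#' @return Fraction in `[0, 1]`.
#' @export
subset_accuracy <- function(cm, row_subset, mode = c("micro", "macro")) {
  stopifnot(inherits(cm, "confusion_matrix"), length(row_subset) > 0L)
  mode <- match.arg(mode)
  missing <- setdiff(row_subset, rownames(cm))
  if (length(missing) > 0L) {
    stop(sprintf("unknown label(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sub <- unclass(cm)[row_subset, , drop = FALSE]
  row_tot <- rowSums(sub)
  if (any(row_tot == 0)) stop("subset rows must have positive totals", call. = FALSE)
  diag_counts <- sub[cbind(seq_along(row_subset),
                           match(row_subset, colnames(cm)))]
  if (mode == "micro") sum(diag_counts) / sum(row_tot)
  else mean(diag_counts / row_tot)
}

#' Per-class recall
#'
#' Diagonal count over row total for each known class. Classes with zero
#' row total are returned as `NA` (undefined), not 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector.
#' @export
per_class_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  tot <- rowSums(m)
  out <- ifelse(tot > 0, diag(m) / tot, NA_real_)
  names(out) <- rownames(m)
  out
}

#' Near-miss rate among misclassifications
#'
#' Fraction of misclassified samples whose predicted genotype is a "near
#' miss" of the truth (shares one allele, other allele off by one repeat;
#' see [near_genotypes()]). Returns `NA` when the matrix has no
#' misclassifications.
#'
#' @param cm A `confusion_matrix` whose labels parse as genotypes.
#' @return Fraction of off-diagonal counts, or `NA`.
#' @export
near_miss_rate <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  labs <- rownames(m)
  genos <- lapply(labs, parse_genotype)
  off_total <- sum(m) - sum(diag(m))
  if (off_total == 0) return(NA_real_)
  near_count <- 0L
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i != j && m[i, j] > 0 && near_genotypes(genos[[i]], genos[[j]])) {
        near_count <- near_count + m[i, j]
      }
    }
  }
  near_count / off_total
}

#' Random-chance accuracy for a panel of classes
#'
#' @param n_classes Number of classes (>= 1).
#' @return `1 / n_classes`.
#' @export
chance_rate <- function(n_classes) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  1 / n_classes
}
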