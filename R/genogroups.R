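#' Geno-group schemes
#'
#' A geno-group scheme merges genotypes into coarser class labels, trading
#' genotype resolution for prediction accuracy: misclassifications between
#' genotypes in the same group become correct at the group level. A scheme
#' maps every genotype of a panel to exactly one group.
#'
#' @param name Scheme identifier, e.g. `"D5S818-OptionA"`.
#' @param groups Named list: group label -> character vector of genotype
#'   labels. Groups must be disjoint.
#' @return A `"geno_group_scheme"` list with `name`, `groups` and the flat
#'   `mapping` (genotype -> group).
#' @export
geno_group_scheme <- function(name, groups) {
  stopifnot(is.character(name), is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)))
  all_genos <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_genos)) {
    stop("groups must be disjoint: a genotype appears in more than one group",
         call. = FALSE)
  }
  mapping <- rep(names(groups), lengths(groups))
  names(mapping) <- all_genos
  structure(list(name = name, groups = groups, mapping = mapping),
            class = "geno_group_scheme")
}

#' @export
print.geno_group_scheme <- function(x, ...) {
  cat(sprintf("<geno_group_scheme %s: %d groups over %d genotypes>\n",
              x$name, length(x$groups), length(x$mapping)))
  for (g in names(x$groups)) {
    cat(sprintf("  %s: %s\n", g, paste(x$groups[[g]], collapse = " ")))
  }
  invisible(x)
}

#' Map genotype labels to group labels under a scheme
#'
#' @param scheme A [geno_group_scheme()].
#' @param labels Genotype labels.
#' @return Group labels.
#' @export
apply_scheme <- function(scheme, labels) {
  stopifnot(inherits(scheme, "geno_group_scheme"))
  missing <- setdiff(unique(labels), names(scheme$mapping))
  if (length(missing) > 0L) {
    stop(sprintf("scheme '%s' does not map: %s", scheme$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unname(scheme$mapping[labels])
}

#' Collapse a confusion matrix by a geno-group scheme
#'
#' Counts are summed into group cells; the grand total is conserved, and the
#' collapsed accuracy can never be lower than the original (within-group
#' errors move onto the diagonal, nothing leaves it).
#'
#' @param cm A `confusion_matrix` whose labels the scheme covers.
#' @param scheme A [geno_group_scheme()].
#' @return A `confusion_matrix` over group labels, in the scheme's group
#'   order.
#' @export
collapse_confusion <- function(cm, scheme) {
  stopifnot(inherits(cm, "confusion_matrix"))
  grp <- apply_scheme(scheme, rownames(cm))
  glab <- names(scheme$groups)
  out <- matrix(0L, length(glab), length(glab),
                dimnames = list(known = glab, predicted = glab))
  m <- unclass(cm)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[grp[i], grp[j]] <- out[grp[i], grp[j]] + m[i, j]
    }
  }
  as_confusion(out)
}

#' Published geno-group schemes for D5S818 and D18S51
#'
#' The eleven named grouping options evaluated in the source study: six for
#' D5S818 (options A, B, C, F, H, J) and five for D18S51 (options A, C, E,
#' F, G). These are packaged in `inst/extdata/geno_group_schemes.json`.
#'
#' @param locus `"D5S818"` or `"D18S51"`.
#' @return Named list of [geno_group_scheme()] objects.
#' @export
str_geno_group_schemes <- function(locus = c("D5S818", "D18S51")) {
  locus <- match.arg(locus)
  path <- system.file("extdata", "geno_group_schemes.json", package = "meltSTR")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)[[locus]]
  out <- lapply(names(raw), function(opt) {
    groups <- lapply(raw[[opt]], function(g) unlist(g))
    geno_group_scheme(sprintf("%s-Option%s", locus, opt), groups)
  })
  names(out) <- names(raw)
  out
}

#' Identity scheme over a label set
#'
#' Maps every genotype to its own group; collapsing by it is a no-op.
#'
#' @param labels Genotype labels.
#' @return A [geno_group_scheme()].
#' @export
identity_scheme <- function(labels) {
  groups <- as.list(labels)
  names(groups) <- labels
  geno_group_scheme("identity", groups)
}

#' Compare geno-group schemes under both evaluation protocols
#'
#' For each scheme, computes group-level accuracy under:
#' \itemize{
#'   \item `collapse`: classify at genotype level, then collapse the
#'     confusion matrix post hoc;
#'   \item `retrain`: re-label the standards with group labels, refit the
#'     classifier, and predict groups directly.
#' }
#' Both are offered because published comparisons ("converse method") do not
#' pin down which was used; they generally differ, since retraining changes
#' the fitted class structure.
#'
#' @param train_x,train_labels Training feature matrix (or list of
#'   normalized curves for `classifier = "pca"`) and genotype labels.
#' @param test_x,test_labels Held-out features/curves and true genotype
#'   labels.
#' @param schemes Named list of [geno_group_scheme()] objects.
#' @param classifier `"lda"` or `"pca"`.
#' @param protocols Character subset of `c("collapse", "retrain")`.
#' @param ... Passed to [fit_lda()] or [fit_pca_typing()].
#' @return Data frame with columns `scheme`, `protocol`, `n_groups`,
#'   `accuracy`, plus a `"confusions"` attribute holding each run's group
#'   confusion matrix.
#' @export
evaluate_grouping_options <- function(train_x, train_labels, test_x, test_labels,
                                      schemes, classifier = c("lda", "pca"),
                                      protocols = c("collapse", "retrain"), ...) {
  classifier <- match.arg(classifier)
  protocols <- match.arg(protocols, c("collapse", "retrain"), several.ok = TRUE)
  fit_fun <- function(x, labs) {
    if (classifier == "lda") fit_lda(x, labs, ...) else fit_pca_typing(x, labs, ...)
  }
  predict_fun <- function(model, x) {
    if (classifier == "lda") predict_lda(model, x)$label
    else vapply(x, function(cu) type_unknown(model, cu)$label, character(1L))
  }
  rows <- list()
  confusions <- list()
  base_model <- NULL
  for (si in seq_along(schemes)) {
    sc <- schemes[[si]]
    sname <- if (!is.null(names(schemes))) names(schemes)[si] else sc$name
    for (proto in protocols) {
      if (proto == "collapse") {
        if (is.null(base_model)) base_model <- fit_fun(train_x, train_labels)
        pred <- predict_fun(base_model, test_x)
        keep <- pred != "UNCLASSIFIED"
        cm <- build_confusion(test_labels[keep], pred[keep],
                              sort(unique(c(test_labels, train_labels))))
        gcm <- collapse_confusion(cm, sc)
      } else {
        gmodel <- fit_fun(train_x, apply_scheme(sc, train_labels))
        pred <- predict_fun(gmodel, test_x)
        keep <- pred != "UNCLASSIFIED"
        gcm <- build_confusion(apply_scheme(sc, test_labels[keep]), pred[keep],
                               names(sc$groups))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(scheme = sname, protocol = proto,
                   n_groups = length(sc$groups), accuracy = accuracy(gcm),
                   stringsAsFactors = FALSE)
      confusions[[paste(sname, proto, sep = ".")]] <- gcm
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "confusions") <- confusions
  out
}
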