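# Expression preprocessing: low-expression filtering and outlier-section
# detection. Filtering precedes outlier removal and is not re-run after
# sections are dropped, so reported gene counts refer to the full section set.

#' Filter lowly expressed genes
#'
#' Retains exactly the genes whose number of sections with RPKM strictly above
#' `rpkm_cut` is strictly greater than `frac` times the section count. At the
#' defaults (RPKM > 1 in more than 10\% of sections) this keeps genes observed
#' above 1 RPKM in at least 2 sections for any leaf gradient of 10 to 15
#' sections (see [min_retained_sections()]).
#'
#' @param mat An `expression_matrix`.
#' @param rpkm_cut Expression cutoff (default 1 RPKM).
#' @param frac Fraction of sections that must exceed the cutoff (default 0.10,
#'   applied as a strict inequality).
#' @return The filtered `expression_matrix`; the section set is unchanged.
#' @export
filter_low_expression <- function(mat, rpkm_cut = 1, frac = 0.10) {
  stopifnot(inherits(mat, "expression_matrix"), frac > 0, frac < 1)
  n_above <- rowSums(mat$values > rpkm_cut)
  keep <- n_above > frac * ncol(mat$values)
  if (!any(keep)) {
    stop("low-expression filter removed all genes; review rpkm_cut/frac")
  }
  expression_matrix(mat$values[keep, , drop = FALSE], mat$species_code)
}

#' Detect outlier sections by sample clustering
#'
#' Sections are compared through the Pearson correlation of their
#' log2(RPKM + 1) expression profiles across genes. A section is flagged as an
#' outlier when its maximum correlation to any other section falls below
#' `min_cor`; a zero-variance (constant) section is flagged with the distinct
#' reason code `"degenerate"`. This reproduces the common situation where the
#' basal-most leaf section, transcriptionally unlike the rest of the gradient,
#' is removed before network construction.
#'
#' @param mat An `expression_matrix` (at least 3 sections; a warning is issued
#'   below 50 genes, where section correlations are unstable).
#' @param min_cor Flagging threshold on the maximum inter-section correlation
#'   (default 0.6).
#' @return List with `outliers` (character vector of section labels),
#'   `reasons` (named character vector, `"low_correlation"` or `"degenerate"`)
#'   and `cor_matrix` (the full section-section correlation matrix).
#' @export
detect_outlier_sections <- function(mat, min_cor = 0.6) {
  stopifnot(inherits(mat, "expression_matrix"))
  v <- mat$values
  if (nrow(v) < 50L) {
    warning("fewer than 50 genes: section correlations may be unstable")
  }
  lv <- log2(v + 1)
  sds <- apply(lv, 2L, stats::sd)
  degenerate <- colnames(v)[sds == 0]
  cm <- suppressWarnings(stats::cor(lv))
  diag(cm) <- NA_real_
  max_cor <- apply(cm, 2L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) -Inf else max(x)
  })
  low <- setdiff(colnames(v)[max_cor < min_cor], degenerate)
  reasons <- c(stats::setNames(rep("degenerate", length(degenerate)), degenerate),
               stats::setNames(rep("low_correlation", length(low)), low))
  flagged <- colnames(v)[colnames(v) %in% c(degenerate, low)]
  diag(cm) <- 1
  list(outliers = flagged, reasons = reasons[flagged], cor_matrix = cm)
}

#' Drop sections from an expression matrix
#'
#' @param mat An `expression_matrix`.
#' @param labels Section labels to remove (must all be present); the order of
#'   the remaining sections is preserved.
#' @return The reduced `expression_matrix`.
#' @export
drop_sections <- function(mat, labels) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (length(labels) == 0L) return(mat)
  unknown <- setdiff(labels, section_labels(mat))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown section label(s): %s", paste(unknown, collapse = ", ")))
  }
  keep <- setdiff(section_labels(mat), labels)
  if (length(keep) < 3L) {
    stop("dropping these sections would leave fewer than 3 sections")
  }
  expression_matrix(mat$values[, keep, drop = FALSE], mat$species_code)
}
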