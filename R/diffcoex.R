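# Differential co-expression between a C4 species and the C3 reference:
# a change adjacency built from signed squared correlation differences,
# TOM-based dissimilarity, branch-cut clustering, a sign-separation step that
# splits gain-of-correlation from loss-of-correlation genes, and the retention
# thresholds (module size >= 30, |delta r| > 0.7 in more than 10% of pairs).

DIFF_DIRECTIONS <- c("higher_in_C4", "lower_in_C4")

#' Differential co-expression dissimilarity
#'
#' The change adjacency between genes i and j is
#' `c_ij = ( |sign(rA_ij) rA_ij^2 - sign(rB_ij) rB_ij^2| / 2 )^(beta/2)`,
#' i.e. the halved absolute difference of signed squared correlations between
#' the two species, soft-thresholded with power `beta`. The returned
#' dissimilarity is `1 - TOM(c)` (see [compute_tom()]): gene pairs whose
#' correlation structure changed consistently, together with shared changed
#' neighbours, end up close.
#'
#' @param cor_a,cor_b Correlation matrices of the two species over the same
#'   ordered orthologue-pair gene set (identical dimnames required;
#'   conventionally A = C4 species, B = C3 reference).
#' @param beta Soft power for the change adjacency (default 6).
#' @return Dissimilarity matrix in \[0, 1\] with attribute
#'   `change_adjacency`.
#' @export
diff_dissimilarity <- function(cor_a, cor_b, beta = 6L) {
  stopifnot(is.matrix(cor_a), is.matrix(cor_b))
  if (!identical(dimnames(cor_a), dimnames(cor_b)) ||
      !identical(dim(cor_a), dim(cor_b))) {
    stop("cor_a and cor_b must cover the same ordered gene set")
  }
  cadj <- (abs(sign(cor_a) * cor_a^2 - sign(cor_b) * cor_b^2) / 2)^(beta / 2)
  diag(cadj) <- 0
  d <- 1 - compute_tom(cadj)
  attr(d, "change_adjacency") <- cadj
  d
}

#' Construct a differential module partition
#'
#' @param labels Named character vector gene -> module label ("unassigned"
#'   for genes in no differential module).
#' @param direction Named character vector module -> direction
#'   ("higher_in_C4" / "lower_in_C4").
#' @param pair Character vector `c(c4, c3)` of species codes (optional).
#' @param qualifying_fraction Named numeric vector module -> fraction of
#'   within-module pairs with `|delta r|` above the retention threshold
#'   (filled by [filter_diff_modules()]).
#' @return Object of class `diff_module_partition`.
#' @export
diff_module_partition <- function(labels, direction = character(0),
                                  pair = c(NA_character_, NA_character_),
                                  qualifying_fraction = numeric(0)) {
  stopifnot(is.character(labels), !is.null(names(labels)))
  structure(list(labels = labels, direction = direction, pair = pair,
                 qualifying_fraction = qualifying_fraction),
            class = "diff_module_partition")
}

#' @export
print.diff_module_partition <- function(x, ...) {
  mods <- setdiff(unique(x$labels), "unassigned")
  cat(sprintf("diff_module_partition: %s vs %s, %d genes, %d modules\n",
              x$pair[1L], x$pair[2L], length(x$labels), length(mods)))
  for (m in mods) {
    cat(sprintf("  %s: %d genes, %s\n", m, sum(x$labels == m),
                if (m %in% names(x$direction)) x$direction[m] else "?"))
  }
  invisible(x)
}

#' Detect differential co-expression modules (pre-filter)
#'
#' Average-linkage clustering of the differential dissimilarity with the same
#' branch-cut engine used for co-expression modules, followed by the
#' sign-separation step: inside every cluster, genes are split by the sign of
#' their mean signed correlation change `sum_j (rA_ij - rB_ij)` restricted to
#' cluster members, and each sign group is kept as a separate module only if
#' it still has `min_size` genes (smaller groups become unassigned). This
#' separates genes gaining correlation in the C4 species from genes losing
#' it, which the plain change adjacency (being unsigned) mixes.
#'
#' @param dissim Output of [diff_dissimilarity()].
#' @param cor_a,cor_b The two correlation matrices (A = C4, B = C3).
#' @param min_size Minimum module size (default 30).
#' @param pair Character vector `c(c4, c3)` of species codes, used for module
#'   label prefixes (e.g. "MR.turquoise").
#' @param ... Passed to [detect_modules()] (cut parameters).
#' @return A `diff_module_partition` with per-module directions; apply
#'   [filter_diff_modules()] to enforce the retention thresholds.
#' @export
detect_diff_modules <- function(dissim, cor_a, cor_b, min_size = 30L,
                                pair = c(NA_character_, NA_character_), ...) {
  part <- suppressWarnings(
    detect_modules(dissim, min_module_size = min_size, ...)
  )
  ids <- names(part$labels)
  delta <- cor_a - cor_b
  out <- stats::setNames(rep("unassigned", length(ids)), ids)
  groups <- list()
  for (m in names(module_sizes(part))) {
    members <- module_members(part, m)
    dsub <- delta[members, members, drop = FALSE]
    diag(dsub) <- 0
    s <- rowSums(dsub)
    pos <- members[s >= 0]
    neg <- members[s < 0]
    if (length(pos) >= min_size) groups[[length(groups) + 1L]] <- pos
    if (length(neg) >= min_size) groups[[length(groups) + 1L]] <- neg
  }
  direction <- character(0)
  if (length(groups) > 0L) {
    ord <- order(-vapply(groups, length, integer(1L)),
                 vapply(groups, function(g) sort(g)[1L], character(1L)))
    groups <- groups[ord]
    prefix <- if (is.na(pair[1L])) "" else paste0(pair[1L], pair[2L], ".")
    labs <- paste0(prefix, if (length(groups) <= length(MODULE_COLOURS)) {
      MODULE_COLOURS[seq_along(groups)]
    } else {
      c(MODULE_COLOURS, paste0("module", seq(length(MODULE_COLOURS) + 1L,
                                             length(groups))))[seq_along(groups)]
    })
    for (i in seq_along(groups)) {
      out[groups[[i]]] <- labs[i]
      direction[labs[i]] <- module_direction(groups[[i]], cor_a, cor_b)
    }
  }
  diff_module_partition(out, direction, pair)
}

#' Direction of a differential module
#'
#' `"higher_in_C4"` when the mean over within-module gene pairs of
#' `rA_ij - rB_ij` is positive (A = C4 species, B = C3 reference), otherwise
#' `"lower_in_C4"`; an exact zero mean is labelled `"higher_in_C4"` with a
#' warning.
#'
#' @param members Gene ids of the module (at least 2).
#' @param cor_a,cor_b Correlation matrices covering the members.
#' @return One of `"higher_in_C4"`, `"lower_in_C4"`.
#' @export
module_direction <- function(members, cor_a, cor_b) {
  if (length(members) < 2L) stop("a module direction needs at least 2 genes")
  d <- (cor_a - cor_b)[members, members]
  m <- mean(d[upper.tri(d)])
  if (m == 0) {
    warning("mean correlation change is exactly zero; labelling higher_in_C4")
    return("higher_in_C4")
  }
  if (m > 0) "higher_in_C4" else "lower_in_C4"
}

#' Retain differential modules passing the published thresholds
#'
#' Keeps modules with at least `min_size` genes whose fraction of
#' within-module gene pairs with `|rA_ij - rB_ij| > delta` is strictly
#' greater than `frac_cut` (defaults: correlation difference above 0.7 in
#' more than 10\% of pairs, at least 30 genes). Discarded modules'' genes
#' become unassigned.
#'
#' @param part A `diff_module_partition` from [detect_diff_modules()].
#' @param cor_a,cor_b The two correlation matrices.
#' @param delta Correlation-difference threshold (default 0.7).
#' @param frac_cut Required fraction of qualifying pairs (default 0.10,
#'   strict).
#' @param min_size Minimum module size (default 30).
#' @return The filtered `diff_module_partition`; `qualifying_fraction` holds
#'   the per-module fractions of retained modules.
#' @export
filter_diff_modules <- function(part, cor_a, cor_b, delta = 0.7,
                                frac_cut = 0.10, min_size = 30L) {
  stopifnot(inherits(part, "diff_module_partition"))
  mods <- setdiff(unique(part$labels), "unassigned")
  out <- part$labels
  keep_dir <- character(0)
  keep_frac <- numeric(0)
  for (m in sort(mods)) {
    members <- names(part$labels)[part$labels == m]
    if (length(members) < min_size) {
      out[members] <- "unassigned"
      next
    }
    d <- abs(cor_a - cor_b)[members, members]
    frac <- mean(d[upper.tri(d)] > delta)
    if (frac > frac_cut) {
      keep_dir[m] <- part$direction[m]
      keep_frac[m] <- frac
    } else {
      out[members] <- "unassigned"
    }
  }
  diff_module_partition(out, keep_dir, part$pair, keep_frac)
}
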