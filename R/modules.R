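# Module detection on a TOM dissimilarity, module eigengenes, and eigengene
# based module merging. A module partition assigns every gene exactly one
# label; "grey" is the reserved label for unassigned genes and never carries
# an eigengene.

#' Construct a module partition
#'
#' @param labels Named character vector gene id -> module label ("grey" =
#'   unassigned).
#' @param species_code Species the partition belongs to (optional).
#' @param eigengenes Optional sections-by-modules matrix of module eigengenes.
#' @param dendrogram Optional `hclust` object the partition was cut from.
#' @return Object of class `module_partition`.
#' @export
module_partition <- function(labels, species_code = NA_character_,
                             eigengenes = NULL, dendrogram = NULL) {
  stopifnot(is.character(labels), !is.null(names(labels)))
  if (anyDuplicated(names(labels))) stop("duplicate gene ids in partition")
  structure(list(species_code = species_code, labels = labels,
                 eigengenes = eigengenes, dendrogram = dendrogram),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat(sprintf("module_partition: species %s, %d genes, %d modules (%d unassigned)\n",
              x$species_code, length(x$labels), length(sz),
              sum(x$labels == UNASSIGNED_LABEL)))
  if (length(sz) > 0L) print(sz)
  invisible(x)
}

#' Module sizes of a partition (unassigned excluded)
#' @param part A `module_partition`.
#' @return Named integer vector, decreasing.
#' @export
module_sizes <- function(part) {
  labs <- part$labels[part$labels != UNASSIGNED_LABEL]
  if (length(labs) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- sort(table(labs), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' Member genes of one module
#' @param part A `module_partition`.
#' @param label Module label.
#' @return Character vector of gene ids.
#' @export
module_members <- function(part, label) {
  names(part$labels)[part$labels == label]
}

#' Detect modules by dynamic branch cutting
#'
#' Average-linkage hierarchical clustering of a TOM dissimilarity followed by
#' a deterministic dynamic branch cut (height ceiling at the 99th percentile
#' of merge heights, merge-gap splitting, median-tightness acceptance; see the
#' methods vignette). Branches smaller than `min_module_size` are assigned
#' "grey". Module labels are colour names ordered by decreasing size. Genes
#' are ordered lexicographically before clustering so that dendrogram ties are
#' broken reproducibly.
#'
#' @param dissim Symmetric dissimilarity matrix in \[0, 1\] with gene ids as
#'   dimnames (typically `1 - compute_tom(adj)`).
#' @param min_module_size Minimum module size (default 30).
#' @param species_code Optional species label stored in the partition.
#' @param cut_quantile Quantile of merge heights used as the cut ceiling
#'   (default 0.99).
#' @param core_frac Acceptance fraction: a branch becomes a module when its
#'   median pairwise dissimilarity is at most `core_frac` times the matrix-wide
#'   median (default 0.97).
#' @param min_gap Minimum merge-height gap that splits two candidate branches
#'   (default 0.15).
#' @return A `module_partition` (eigengenes not yet attached; see
#'   [add_module_eigengenes()]).
#' @export
detect_modules <- function(dissim, min_module_size = 30L,
                           species_code = NA_character_, cut_quantile = 0.99,
                           core_frac = 0.97, min_gap = 0.15) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  ids <- rownames(dissim)
  if (is.null(ids)) stop("dissimilarity matrix must carry gene ids as dimnames")
  if (max(abs(dissim - t(dissim))) > 1e-8) stop("dissimilarity must be symmetric")
  n <- nrow(dissim)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: all genes unassigned")
    return(module_partition(stats::setNames(rep(UNASSIGNED_LABEL, n), ids),
                            species_code))
  }
  ord <- order(ids)
  d <- dissim[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ints <- cut_tree_modules(hc, d, min_size = min_module_size,
                           cut_quantile = cut_quantile, core_frac = core_frac,
                           min_gap = min_gap)
  cols <- size_ordered_labels(ints)
  labels <- stats::setNames(rep(UNASSIGNED_LABEL, n), ids)
  labels[ids[ord]] <- cols
  module_partition(labels, species_code, dendrogram = hc)
}

#' Module eigengene
#'
#' First principal component of the member genes' section profiles after
#' per-gene standardization (mean 0, sd 1) of the transformed expression.
#' The eigengene has unit norm and is oriented so that its mean correlation
#' with the member profiles is non-negative (with a deterministic
#' first-nonzero-positive rule when that mean is exactly zero).
#'
#' @param mat An `expression_matrix` containing the member genes.
#' @param member_genes At least 2 gene ids; members with zero variance are
#'   excluded with a warning (an error if all are).
#' @param transform Expression transform, as in [build_correlation()].
#' @return Numeric vector over the sections with unit norm; attribute
#'   `var_explained` holds the fraction of variance captured by the first
#'   component.
#' @export
module_eigengene <- function(mat, member_genes, transform = c("log2p1", "none")) {
  stopifnot(inherits(mat, "expression_matrix"))
  transform <- match.arg(transform)
  if (length(member_genes) < 2L) stop("an eigengene needs at least 2 member genes")
  missing <- setdiff(member_genes, gene_ids(mat))
  if (length(missing) > 0L) {
    stop(sprintf("member gene(s) not in matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  x <- mat$values[member_genes, , drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  z <- standardize_rows(x)
  zero <- attr(z, "zero_variance")
  if (length(zero) > 0L) {
    warning(sprintf("excluding %d zero-variance member(s)", length(zero)))
    z <- z[setdiff(rownames(z), zero), , drop = FALSE]
    if (nrow(z) == 0L) stop("all member genes have zero variance")
  }
  sv <- svd(z)
  v <- sv$v[, 1L]
  v <- v / sqrt(sum(v^2))
  cors <- suppressWarnings(apply(z, 1L, function(g) stats::cor(g, v)))
  mean_cor <- mean(cors, na.rm = TRUE)
  if (is.na(mean_cor) || mean_cor == 0) {
    nz <- which(abs(v) > 1e-12)[1L]
    if (!is.na(nz) && v[nz] < 0) v <- -v
  } else if (mean_cor < 0) {
    v <- -v
  }
  names(v) <- section_labels(mat)
  attr(v, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  v
}

#' Attach eigengenes to a module partition
#'
#' Computes the eigengene of every non-grey module of `part` from `mat` and
#' stores them as a sections-by-modules matrix in the partition. A
#' single-gene module (possible at `min_module_size = 1`) gets its
#' standardized, unit-norm profile.
#'
#' @param part A `module_partition`.
#' @param mat The `expression_matrix` the partition was derived from.
#' @param transform Expression transform, as in [build_correlation()].
#' @return The partition with `eigengenes` filled in.
#' @export
add_module_eigengenes <- function(part, mat, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  mods <- names(module_sizes(part))
  if (length(mods) == 0L) {
    part$eigengenes <- NULL
    return(part)
  }
  E <- matrix(NA_real_, nrow = ncol(mat$values), ncol = length(mods),
              dimnames = list(section_labels(mat), mods))
  for (mlab in mods) {
    members <- module_members(part, mlab)
    if (length(members) == 1L) {
      x <- mat$values[members, ]
      if (transform == "log2p1") x <- log2(x + 1)
      z <- (x - mean(x)) / stats::sd(x)
      E[, mlab] <- z / sqrt(sum(z^2))
    } else {
      E[, mlab] <- module_eigengene(mat, members, transform)
    }
  }
  part$eigengenes <- E
  part
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene Pearson
#' correlation while that correlation is at least `merge_cor` (default 0.9),
#' recomputing the merged eigengene each round. Ties on the maximal
#' correlation are broken towards the pair with the larger combined size, then
#' lexicographically. Unassigned ("grey") genes are never touched; labels are
#' re-assigned by decreasing size at the end.
#'
#' @param part A `module_partition` (eigengenes are computed if absent).
#' @param mat The `expression_matrix` the partition was derived from.
#' @param merge_cor Merge threshold on the eigengene correlation (default
#'   0.9).
#' @param transform Expression transform, as in [build_correlation()].
#' @return The merged `module_partition` with refreshed eigengenes.
#' @export
merge_modules <- function(part, mat, merge_cor = 0.9,
                          transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (is.null(part$eigengenes)) part <- add_module_eigengenes(part, mat, transform)
  members <- lapply(stats::setNames(nm = names(module_sizes(part))),
                    function(l) module_members(part, l))
  eigs <- lapply(stats::setNames(nm = names(members)),
                 function(l) part$eigengenes[, l])

  while (length(members) >= 2L) {
    labs <- names(members)
    E <- do.call(cbind, eigs[labs])
    C <- suppressWarnings(stats::cor(E))
    diag(C) <- -Inf
    C[is.na(C)] <- -Inf
    best <- max(C)
    if (best < merge_cor) break
    idx <- which(C >= best - 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    combined <- vapply(seq_len(nrow(idx)), function(i) {
      length(members[[labs[idx[i, 1L]]]]) + length(members[[labs[idx[i, 2L]]]])
    }, numeric(1L))
    pair_key <- vapply(seq_len(nrow(idx)), function(i) {
      paste(sort(c(labs[idx[i, 1L]], labs[idx[i, 2L]])), collapse = "|")
    }, character(1L))
    pick <- order(-combined, pair_key)[1L]
    a <- labs[idx[pick, 1L]]; b <- labs[idx[pick, 2L]]
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
    eigs[[b]] <- NULL
    eigs[[a]] <- module_eigengene(mat, members[[a]], transform)
  }

  # relabel by decreasing size (ties: previous label, lexicographic)
  sizes <- vapply(members, length, integer(1L))
  ord <- order(-sizes, names(members))
  new_names <- if (length(ord) <= length(MODULE_COLOURS)) {
    MODULE_COLOURS[seq_along(ord)]
  } else {
    c(MODULE_COLOURS,
      paste0("module", seq(length(MODULE_COLOURS) + 1L, length(ord))))[seq_along(ord)]
  }
  labels <- part$labels
  E_new <- NULL
  if (length(ord) > 0L) {
    E_new <- matrix(NA_real_, nrow = ncol(mat$values), ncol = length(ord),
                    dimnames = list(section_labels(mat), new_names))
    for (i in seq_along(ord)) {
      old <- names(members)[ord[i]]
      labels[members[[old]]] <- new_names[i]
      E_new[, new_names[i]] <- eigs[[old]]
    }
  }
  module_partition(labels, part$species_code, eigengenes = E_new,
                   dendrogram = part$dendrogram)
}
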