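# Internal helpers shared across the pipeline stages.

#' Module colour vocabulary
#'
#' Ordered colour names used to label co-expression modules by decreasing size,
#' following the naming convention of weighted co-expression analyses ("grey"
#' is reserved for unassigned genes and never appears here). When a partition
#' has more modules than colours, numbered labels ("module41", ...) are used.
#'
#' @format Character vector of colour names.
#' @export
MODULE_COLOURS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3", "lightsteelblue1", "floralwhite",
  "ivory", "brown4"
)

#' Reserved label for unassigned genes
#' @export
UNASSIGNED_LABEL <- "grey"

# Map integer cluster ids (0 = unassigned) to size-ordered colour labels.
# Ties in size are broken by the smallest original id so relabelling is
# deterministic.
size_ordered_labels <- function(ids) {
  stopifnot(is.numeric(ids))
  pos <- ids[ids > 0]
  if (length(pos) == 0L) {
    return(rep(UNASSIGNED_LABEL, length(ids)))
  }
  tab <- table(pos)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  ranked <- as.integer(names(tab))[ord]
  labels <- if (length(ranked) <= length(MODULE_COLOURS)) {
    MODULE_COLOURS[seq_along(ranked)]
  } else {
    c(MODULE_COLOURS, paste0("module", seq(length(MODULE_COLOURS) + 1L,
                                           length(ranked))))[seq_along(ranked)]
  }
  out <- rep(UNASSIGNED_LABEL, length(ids))
  out[ids > 0] <- labels[match(ids[ids > 0], ranked)]
  out
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelled partitions of the same items, corrected for
#' chance. Used to score recovered module assignments against planted truth in
#' simulation studies; 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  if (length(a) == 0L) stop("empty partitions")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Standardize rows of a matrix to mean 0, sd 1. Rows with zero variance are
# returned as an attribute so callers can decide (error vs drop).
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  z <- (x - mu) / ifelse(zero, 1, sdv)
  attr(z, "zero_variance") <- rownames(x)[zero]
  z
}

# Strictly-greater count threshold behind the low-expression filter: the
# smallest section count k satisfying k > frac * n.
#' Minimum retained-section count under the expression filter
#'
#' The low-expression filter keeps a gene when its number of sections above the
#' RPKM cutoff is strictly greater than `frac` times the section count. This
#' helper returns the smallest qualifying count for a given number of sections,
#' e.g. 2 for every leaf-gradient design with 10 to 15 sections at the default
#' 10\% fraction.
#'
#' @param n_sections Number of sections.
#' @param frac Fraction of sections (default 0.10).
#' @return Integer, the minimum count of sections above the cutoff that a
#'   retained gene must have.
#' @export
min_retained_sections <- function(n_sections, frac = 0.10) {
  stopifnot(n_sections >= 1, frac > 0, frac < 1)
  as.integer(floor(frac * n_sections)) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
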