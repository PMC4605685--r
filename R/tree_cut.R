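# Deterministic branch decomposition of an average-linkage dendrogram.
#
# A TOM dissimilarity separates scales cleanly: gene pairs inside a
# co-expression module sit far below the background dissimilarity level,
# while unclustered genes differ from everything by roughly that background
# level. Merge heights alone are unreliable here -- average-linkage chains of
# background genes can start from chance-tight pairs at low heights -- so
# branch acceptance is decided on the pairwise dissimilarities themselves.
#
# The cutter walks the tree from the root and decides per branch:
#   * a branch whose merge height exceeds the height ceiling h0 (the
#     `cut_quantile` quantile of all merge heights, default the 99th
#     percentile) is always split;
#   * a branch whose two children are both at least `min_size` large and
#     whose merge height exceeds the children's own heights by at least
#     `min_gap` is split -- this separates distinct tight modules that happen
#     to join below the ceiling;
#   * otherwise the branch is accepted as a module iff the median of its
#     pairwise dissimilarities is at most `core_frac` times the background
#     level D0 (the median pairwise dissimilarity of the whole matrix):
#     a real module is tight relative to the bulk; rejected branches are
#     explored further down.
# An accepted branch is then pruned: members whose median dissimilarity to
# the other members lies closer to the background level D0 than to the
# branch's own median (i.e. beyond the midpoint of the two) are returned to
# the unassigned pool (average-linkage accretion drags loosely attached genes
# into tight branches; pruning keeps only genes genuinely close to the
# module). A branch falling below `min_size` after pruning is discarded.
# Genes in no accepted branch, and branches smaller than `min_size`, stay
# unassigned (0). The procedure is fully deterministic given the dendrogram.

cut_tree_modules <- function(hc, dissim, min_size = 30L, cut_quantile = 0.99,
                             core_frac = 0.97, min_gap = 0.15) {
  n <- length(hc$order)
  labels <- integer(n)
  if (n < 2L) return(labels)
  m <- hc$merge
  h <- hc$height
  nm <- nrow(m)
  h0 <- as.numeric(stats::quantile(h, cut_quantile, type = 7))
  d0 <- stats::median(dissim[upper.tri(dissim)])
  accept_cut <- core_frac * d0

  size <- integer(nm)
  leaves <- vector("list", nm)
  for (i in seq_len(nm)) {
    l <- m[i, 1L]; r <- m[i, 2L]
    leaves[[i]] <- c(if (l < 0L) -l else leaves[[l]],
                     if (r < 0L) -r else leaves[[r]])
    size[i] <- length(leaves[[i]])
  }

  median_within <- function(i) {
    g <- leaves[[i]]
    d <- dissim[g, g]
    stats::median(d[upper.tri(d)])
  }

  next_id <- 0L
  stack <- nm
  min_child <- max(min_size, 2L)
  while (length(stack) > 0L) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (size[i] < min_size) next
    l <- m[i, 1L]; r <- m[i, 2L]
    kids <- c(l, r)[c(l, r) > 0L]
    branch_med <- median_within(i)
    if (h[i] > h0 ||
        (l > 0L && r > 0L && size[l] >= min_child && size[r] >= min_child &&
         (h[i] - max(h[l], h[r])) >= min_gap) ||
        branch_med > accept_cut) {
      if (length(kids) > 0L) stack <- c(stack, kids)
    } else {
      g <- leaves[[i]]
      if (length(g) > 2L) {
        prune_cut <- (branch_med + d0) / 2
        med_to_branch <- vapply(seq_along(g), function(j) {
          stats::median(dissim[g[j], g[-j]])
        }, numeric(1L))
        g <- g[med_to_branch <= prune_cut]
      }
      if (length(g) >= min_size) {
        next_id <- next_id + 1L
        labels[g] <- next_id
      }
    }
  }
  labels
}
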