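# Independent oracle implementations used to verify the package's numerics.
# These deliberately use naive textbook formulations (loops, direct sums)
# rather than the vectorized implementations under test.

# Topological overlap by a literal triple loop over the defining formula.
oracle_tom <- function(adj) {
  n <- nrow(adj)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(adj[i, ])
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- 1
      } else {
        l <- sum(adj[i, ] * adj[, j])   # loop over shared neighbours u
        out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
      }
    }
  }
  out
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf written
# with binomial coefficients.
oracle_hyper_tail <- function(k, n_a, n_b, big_n) {
  hi <- min(n_a, n_b)
  if (k > hi) return(0)
  j <- seq.int(max(k, max(0L, n_a + n_b - big_n)), hi)
  sum(choose(n_a, j) * choose(big_n - n_a, n_b - j)) / choose(big_n, n_b)
}

# Pearson correlation from the raw covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}

# Benjamini-Hochberg step-up adjustment written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (r in seq.int(m, 1L)) {
    running <- min(running, p[ord[r]] * m / r)
    adj[ord[r]] <- running
  }
  adj
}

# A tiny expression matrix from a genes x sections value matrix.
make_mat <- function(values, species = "M", genes = NULL, sections = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(sections)) sections <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, sections)
  expression_matrix(values, species)
}

# Random symmetric adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  a
}

# Block-structured "correlation" matrices for differential co-expression
# tests: blocks is a list of list(idx, r); base fills the rest.
block_cor <- function(n, blocks, base = 0, ids = sprintf("g%04d", seq_len(n))) {
  m <- matrix(base, n, n, dimnames = list(ids, ids))
  for (b in blocks) m[b$idx, b$idx] <- b$r
  diag(m) <- 1
  m
}
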