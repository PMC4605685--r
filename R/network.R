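# Unsigned weighted co-expression network construction: Pearson similarity,
# soft-thresholded adjacency, scale-free fit for power selection, and the
# topological overlap matrix used as clustering (dis)similarity.

#' Published default soft powers per species
#'
#' Soft-thresholding powers rendering each species' leaf-gradient network
#' approximately scale free: maize (M) 10, green foxtail (G) 12, sorghum (S)
#' 18, rice (R) 16.
#'
#' @export
SOFT_POWER_DEFAULTS <- c(M = 10L, G = 12L, S = 18L, R = 16L)

#' Gene-gene Pearson correlation matrix
#'
#' Correlations of gene expression profiles across the ordered leaf sections,
#' optionally after a log2(x + 1) variance-stabilizing transform (the default
#' for RPKM input; use `"none"` for pre-transformed values).
#'
#' @param mat An `expression_matrix` with at least 3 sections.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return Symmetric numeric matrix of Pearson correlations with unit
#'   diagonal, gene ids as dimnames.
#' @export
build_correlation <- function(mat, transform = c("log2p1", "none")) {
  stopifnot(inherits(mat, "expression_matrix"))
  transform <- match.arg(transform)
  x <- mat$values
  if (transform == "log2p1") x <- log2(x + 1)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance gene(s): %s",
                 paste(utils::head(rownames(x)[sds == 0], 5L), collapse = ", ")))
  }
  r <- stats::cor(t(x))
  # clamp tiny floating-point excursions outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Soft-threshold a correlation matrix into an unsigned adjacency
#'
#' Elementwise `a_ij = |r_ij|^beta` with a zero diagonal. Raising the absolute
#' correlation to a power emphasises strong co-expression and suppresses weak,
#' noise-level correlation, pushing the weighted network towards scale-free
#' topology.
#'
#' @param cor_mat Symmetric correlation matrix (entries in \[-1, 1\]).
#' @param beta Positive integer soft power.
#' @return Adjacency matrix in \[0, 1\] with zero diagonal and attribute
#'   `beta`.
#' @export
soft_threshold <- function(cor_mat, beta) {
  stopifnot(is.matrix(cor_mat), length(beta) == 1L, beta >= 1,
            beta == as.integer(beta))
  a <- abs(cor_mat)^beta
  diag(a) <- 0
  attr(a, "beta") <- as.integer(beta)
  a
}

# Scale-free topology fit: R^2 of the log-log regression of binned
# connectivity frequency on mean binned connectivity, signed so that only a
# negative slope (power-law decay) counts. Returns 0 when the regression is
# degenerate (e.g. all connectivities equal).
scale_free_fit <- function(k, n_breaks = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 2L || diff(range(k)) == 0) return(0)
  bins <- cut(k, breaks = n_breaks)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 3L) return(0)
  fit <- stats::lm(log10(freq[ok] / sum(freq[ok])) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2L]
  if (!is.finite(r2) || !is.finite(slope)) return(0)
  -sign(slope) * r2
}

#' Select the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' connectivity `k_i = sum_j a_ij`, and scores the scale-free topology fit
#' (R-squared of the log-log binned frequency regression, counted only under
#' a negative slope). Returns the smallest power reaching `target_r2`; if none
#' does, the power with the best fit is returned with a warning.
#'
#' @param cor_mat Correlation matrix over at least 30 genes.
#' @param candidate_betas Non-empty vector of positive integer powers
#'   (default 1:20).
#' @param target_r2 Fit threshold (default 0.8).
#' @return A single integer power with attribute `fit_table` (data frame of
#'   beta and signed R-squared).
#' @export
select_soft_power <- function(cor_mat, candidate_betas = 1:20, target_r2 = 0.8) {
  stopifnot(length(candidate_betas) >= 1L)
  if (nrow(cor_mat) < 30L) {
    stop("fewer than 30 genes: scale-free fit is not meaningful")
  }
  betas <- sort(unique(as.integer(candidate_betas)))
  fits <- vapply(betas, function(b) {
    a <- soft_threshold(cor_mat, b)
    scale_free_fit(colSums(a))
  }, numeric(1L))
  tab <- data.frame(beta = betas, signed_r2 = fits)
  hit <- which(fits >= target_r2)
  if (length(hit) > 0L) {
    chosen <- betas[hit[1L]]
  } else {
    warning(sprintf("no candidate power reaches scale-free fit %.2f; using best (beta=%d, R2=%.3f)",
                    target_r2, betas[which.max(fits)], max(fits)))
    chosen <- betas[which.max(fits)]
  }
  structure(chosen, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and unit diagonal. Two genes have high topological
#' overlap when they are strongly connected and share the same weighted
#' neighbours; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj Adjacency matrix in \[0, 1\] with zero diagonal.
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
compute_tom <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- colSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  tom <- (tom + t(tom)) / 2   # enforce exact symmetry against FP noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}
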