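# Construct a two-block adjacency: tight within-block, near-zero between.
two_block_dissim <- function(n_per = 50, a_in = 0.9, a_out = 0.01, seed = 3) {
  set.seed(seed)
  n <- 2 * n_per
  a <- matrix(a_out, n, n)
  a[1:n_per, 1:n_per] <- a_in
  a[(n_per + 1):n, (n_per + 1):n] <- a_in
  jitter <- matrix(stats::runif(n * n, 0, 1e-3), n, n)
  a <- pmin(pmax(a + (jitter + t(jitter)) / 2, 0), 1)
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  1 - compute_tom(a)
}

test_that("two planted blocks are recovered exactly", {
  d <- two_block_dissim()
  part <- detect_modules(d, min_module_size = 30L, species_code = "M")
  sz <- module_sizes(part)
  expect_identical(length(sz), 2L)
  expect_identical(unname(sz), c(50L, 50L))
  block <- rep(c("A", "B"), each = 50)
  names(block) <- rownames(d)
  expect_equal(adjusted_rand_index(part$labels[names(block)], block), 1)

  # no singletons appear even at min_module_size = 1
  part1 <- detect_modules(d, min_module_size = 1L)
  expect_identical(length(module_sizes(part1)), 2L)
  expect_equal(adjusted_rand_index(part1$labels[names(block)], block), 1)
})

test_that("degenerate dissimilarities leave all genes unassigned", {
  n <- 40
  a0 <- matrix(0, n, n, dimnames = list(sprintf("g%02d", 1:n),
                                        sprintf("g%02d", 1:n)))
  d0 <- 1 - compute_tom(a0)
  part <- detect_modules(d0)
  expect_true(all(part$labels == UNASSIGNED_LABEL))

  expect_warning(p2 <- detect_modules(d0[1:10, 1:10], min_module_size = 30L),
                 "unassigned")
  expect_true(all(p2$labels == UNASSIGNED_LABEL))
})

test_that("module detection is deterministic", {
  d <- two_block_dissim(seed = 8)
  p1 <- detect_modules(d)
  p2 <- detect_modules(d)
  expect_identical(p1$labels, p2$labels)
  # row/column order of the input does not matter
  perm <- sample(nrow(d))
  p3 <- detect_modules(d[perm, perm])
  expect_identical(p1$labels[names(p3$labels)], p3$labels)
})

test_that("eigengenes are oriented unit-norm first principal components", {
  # rank-1 module: eigengene recovers the shared profile
  p <- c(1, 2, 4, 8, 16, 24)
  v <- 2^rbind(p, p * 0.5 + 1, p * 0.25 + 2) - 1
  mat <- make_mat(v)
  e <- module_eigengene(mat, gene_ids(mat))
  expect_equal(sum(e^2), 1)
  expect_equal(abs(stats::cor(e, p)), 1, tolerance = 1e-8)
  expect_gt(stats::cor(e, p), 0)  # oriented along the members

  # symmetric module {p, -p}: orientation still deterministic
  z <- c(-1, 0, 2, 0, -1, 3)
  v2 <- rbind(10 + z, 10 - z)
  m2 <- make_mat(v2, sections = sprintf("S%02d", 1:6))
  e2a <- module_eigengene(m2, gene_ids(m2), transform = "none")
  e2b <- module_eigengene(m2, gene_ids(m2), transform = "none")
  expect_identical(e2a, e2b)

  # explained variance matches an independent eigendecomposition
  set.seed(21)
  v3 <- matrix(2^stats::rnorm(40 * 9, 4), 40, 9)
  m3 <- make_mat(v3)
  e3 <- module_eigengene(m3, gene_ids(m3))
  z3 <- t(scale(t(log2(v3 + 1))))
  lam <- eigen(crossprod(z3), symmetric = TRUE)$values
  expect_equal(attr(e3, "var_explained"), lam[1] / sum(lam), tolerance = 1e-8)

  # zero-variance members are excluded with a warning
  v4 <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(5, 5, 5, 5))
  expect_warning(module_eigengene(make_mat(v4), c("g01", "g02", "g03"),
                                  transform = "none"), "zero-variance")
  expect_warning(
    expect_error(module_eigengene(make_mat(v4[c(3, 3), ] + 0,
                                           genes = c("a", "b")), c("a", "b"),
                                  transform = "none"), "zero variance"),
    "zero-variance")
})

test_that("eigengene-based merging follows the greedy rule", {
  # three modules sharing one latent profile: all pairwise correlations high,
  # iterative merging collapses them into a single module
  set.seed(13)
  latent <- seq(0, 3, length.out = 12)
  v <- 2^(4 + outer(stats::runif(90, 0.9, 1.1), latent) +
            matrix(stats::rnorm(90 * 12, 0, 0.05), 90, 12))
  mat <- make_mat(v)
  labels <- stats::setNames(rep(c("turquoise", "blue", "brown"), each = 30),
                            gene_ids(mat))
  part <- add_module_eigengenes(module_partition(labels, "M"), mat)
  eg_cor <- stats::cor(part$eigengenes)
  expect_true(all(eg_cor[upper.tri(eg_cor)] > 0.9))
  merged <- merge_modules(part, mat)
  expect_identical(length(module_sizes(merged)), 1L)
  expect_identical(unname(module_sizes(merged)), 90L)

  # uncorrelated eigengenes: nothing merges, grey untouched
  v5 <- 2^(4 + rbind(outer(rep(1, 20), latent),
                     outer(rep(1, 20), latent[c(7:12, 1:6)])) +
             matrix(stats::rnorm(40 * 12, 0, 0.05), 40, 12))
  m5 <- make_mat(v5)
  lab5 <- stats::setNames(c(rep("turquoise", 20), rep("blue", 15),
                            rep(UNASSIGNED_LABEL, 5)), gene_ids(m5))
  p5 <- add_module_eigengenes(module_partition(lab5, "M"), m5)
  merged5 <- merge_modules(p5, m5)
  expect_identical(length(module_sizes(merged5)), 2L)
  expect_identical(sum(merged5$labels == UNASSIGNED_LABEL), 5L)
  expect_identical(names(which(merged5$labels == UNASSIGNED_LABEL)),
                   names(which(lab5 == UNASSIGNED_LABEL)))
  # merging never increases the module count
  expect_lte(length(module_sizes(merged5)), length(module_sizes(p5)))
})
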