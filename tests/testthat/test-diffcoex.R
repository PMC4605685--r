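test_that("the change dissimilarity follows the signed-square formula", {
  ids <- c("a", "b")
  same <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(ids, ids))
  d_same <- diff_dissimilarity(same, same, beta = 6L)
  expect_equal(attr(d_same, "change_adjacency")[1, 2], 0)
  expect_equal(d_same[1, 2], 1)   # TOM of the zero network is zero

  flip <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(ids, ids))
  ones <- matrix(1, 2, 2, dimnames = list(ids, ids))
  expect_equal(attr(diff_dissimilarity(ones, flip, 6L),
                    "change_adjacency")[1, 2], 1)

  a08 <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(ids, ids))
  zero <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(ids, ids))
  expect_equal(attr(diff_dissimilarity(a08, zero, 6L),
                    "change_adjacency")[1, 2], 0.032768)

  bad <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(diff_dissimilarity(a08, bad), "same ordered gene set")
})

test_that("swapping the species leaves the dissimilarity but flips directions", {
  set.seed(41)
  n <- 80
  ca <- block_cor(n, list(list(idx = 1:40, r = 0.9)))
  cb <- block_cor(n, list())
  da <- diff_dissimilarity(ca, cb, 6L)
  db <- diff_dissimilarity(cb, ca, 6L)
  expect_equal(unclass(da), unclass(db), ignore_attr = TRUE)
  members <- rownames(ca)[1:40]
  expect_identical(module_direction(members, ca, cb), "higher_in_C4")
  expect_identical(module_direction(members, cb, ca), "lower_in_C4")
})

test_that("a planted differential block is detected and the null is empty", {
  set.seed(47)
  n <- 1000
  # leaf-gradient-like profile length: 11 sections
  noise <- function() {
    z <- matrix(stats::rnorm(n * 11), n, 11)
    r <- stats::cor(t(z))
    dimnames(r) <- list(sprintf("g%04d", 1:n), sprintf("g%04d", 1:n))
    r
  }
  ca <- noise(); cb <- noise()
  ca[1:60, 1:60] <- 0.9
  diag(ca) <- 1
  d <- diff_dissimilarity(ca, cb, 6L)
  part <- detect_diff_modules(d, ca, cb, min_size = 30L, pair = c("M", "R"))
  planted <- sprintf("g%04d", 1:60)
  in_mod <- part$labels[planted] != "unassigned"
  expect_gte(mean(in_mod), 0.8)
  main <- names(sort(table(part$labels[planted]), decreasing = TRUE))[1L]
  expect_identical(unname(part$direction[main]), "higher_in_C4")

  # identical correlation structure: nothing survives
  d0 <- diff_dissimilarity(ca, ca, 6L)
  p0 <- detect_diff_modules(d0, ca, ca, min_size = 30L)
  expect_identical(unique(p0$labels), "unassigned")
})

test_that("sign separation splits gain and loss genes into two modules", {
  n <- 200
  gain <- 1:30; lose <- 31:60
  ca <- block_cor(n, list(list(idx = 1:60, r = 0.9),
                          list(idx = lose, r = 0.0)))
  cb <- block_cor(n, list(list(idx = 1:60, r = 0.0),
                          list(idx = lose, r = 0.95)))
  d <- diff_dissimilarity(ca, cb, 6L)
  part <- detect_diff_modules(d, ca, cb, min_size = 30L, pair = c("M", "R"))
  ids <- rownames(ca)
  lab_gain <- unique(part$labels[ids[gain]])
  lab_lose <- unique(part$labels[ids[lose]])
  expect_length(lab_gain, 1L)
  expect_length(lab_lose, 1L)
  expect_false(lab_gain == lab_lose)
  expect_identical(unname(part$direction[lab_gain]), "higher_in_C4")
  expect_identical(unname(part$direction[lab_lose]), "lower_in_C4")
})

test_that("retention enforces the size floor and qualifying-pair fraction", {
  mk_part <- function(n_members, n_total = 120) {
    ids <- sprintf("g%04d", seq_len(n_total))
    labels <- stats::setNames(rep("unassigned", n_total), ids)
    labels[seq_len(n_members)] <- "MR.turquoise"
    diff_module_partition(labels,
                          direction = c(MR.turquoise = "higher_in_C4"),
                          pair = c("M", "R"))
  }
  strong <- function(idx, n_total = 120) {
    block_cor(n_total, list(list(idx = idx, r = 0.9)))
  }
  flat <- function(n_total = 120) block_cor(n_total, list())

  # 29 genes with |delta r| = 0.9 everywhere: discarded on size
  p29 <- filter_diff_modules(mk_part(29), strong(1:29), flat())
  expect_identical(unique(p29$labels), "unassigned")

  # 50 genes but only ~5% of pairs above the threshold: discarded on fraction
  ca <- flat()
  sub <- 1:11   # 55 of 1225 pairs ~ 4.5%
  ca[sub, sub] <- 0.9; diag(ca) <- 1
  p50 <- filter_diff_modules(mk_part(50), ca, flat())
  expect_identical(unique(p50$labels), "unassigned")

  # 50 genes, all pairs changed: retained, fraction recorded
  p_ok <- filter_diff_modules(mk_part(50), strong(1:50), flat())
  expect_identical(sum(p_ok$labels == "MR.turquoise"), 50L)
  expect_equal(unname(p_ok$qualifying_fraction["MR.turquoise"]), 1)
  expect_identical(unname(p_ok$direction["MR.turquoise"]), "higher_in_C4")
})

test_that("module direction averages the pairwise correlation changes", {
  ids <- c("a", "b", "c")
  ca <- matrix(c(1, 0.3, 0.1, 0.3, 1, 0.6, 0.1, 0.6, 1), 3, 3,
               dimnames = list(ids, ids))
  cb <- ca
  cb[1, 2] <- cb[2, 1] <- 0.1   # delta +0.2
  cb[1, 3] <- cb[3, 1] <- 0.2   # delta -0.1
  cb[2, 3] <- cb[3, 2] <- 0.1   # delta +0.5
  expect_identical(module_direction(ids, ca, cb), "higher_in_C4")
  expect_warning(dir0 <- module_direction(ids, ca, ca), "zero")
  expect_identical(dir0, "higher_in_C4")
  expect_error(module_direction("a", ca, cb), "at least 2")
})
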