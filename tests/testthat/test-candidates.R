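# Hand-built two-C4-species fixture with known tip-third means, patterns and
# differential support, exercising every classification rule.
candidate_fixture <- function(rpkm_scale = 1) {
  shape <- c(0, 0.1, 0.3, 0.5, 0.9, 1.1)     # rising; tip third = last 2, mean 1
  fall <- rev(shape)
  sections <- sprintf("S%02d", 1:6)
  build <- function(sp, profiles) {
    v <- do.call(rbind, profiles) * rpkm_scale
    dimnames(v) <- list(paste0(sp, seq_along(profiles)), sections)
    expression_matrix(v, sp)
  }
  mats <- list(
    M = build("M", list(shape * 10, shape * 30, shape * 30, shape * 20,
                        shape * 25, shape * 15)),
    S = build("S", list(shape * 10, shape * 24, shape * 40, shape * 18,
                        shape * 22, shape * 12)),
    R = build("R", list(shape * 10, shape * 10, shape * 20.1, fall * 20,
                        shape * 99))   # R5 exists but og6's R6 is missing
  )
  orth <- orthologue_map(data.frame(
    group_id = paste0("og", 1:6),
    M = paste0("M", 1:6),
    S = paste0("S", 1:6),
    R = c("R1", "R2", "R3", "R4", NA, "R6"),
    stringsAsFactors = FALSE), c("M", "S", "R"))
  eig <- as.vector(scale(log2(shape * 10 + 1)))
  eig <- eig / sqrt(sum(eig^2))
  part_of <- function(sp) {
    labels <- stats::setNames(rep("turquoise", 6), paste0(sp, 1:6))
    module_partition(labels, sp,
                     eigengenes = matrix(eig, ncol = 1,
                                         dimnames = list(sections, "turquoise")))
  }
  parts <- list(M = part_of("M"), S = part_of("S"))
  diff_of <- function(pair) {
    labels <- stats::setNames(rep("unassigned", 6), paste0("og", 1:6))
    labels["og4"] <- paste0(pair, ".turquoise")
    dir <- stats::setNames("higher_in_C4", paste0(pair, ".turquoise"))
    diff_module_partition(labels, dir, c(substr(pair, 1, 1), "R"))
  }
  list(mats = mats, orth = orth, parts = parts,
       c4_modules = list(M = "turquoise", S = "turquoise"),
       diff = list(M = diff_of("MR"), S = diff_of("SR")))
}

test_that("profiles resample deterministically onto the relative grid", {
  expect_equal(resample_profile(c(0, 0, 10), n_grid = 4L),
               c(-0.5773503, -0.5773503, 0, 1.1547005), tolerance = 1e-6)

  # linear ramps of different lengths resample to the same line; the sample
  # standardization constant differs slightly with the section count
  ramp10 <- seq(2, 20, length.out = 10)
  ramp14 <- seq(5, 6, length.out = 14)
  expect_gt(stats::cor(resample_profile(ramp10), resample_profile(ramp14)),
            1 - 1e-9)
  expect_equal(resample_profile(ramp10), resample_profile(ramp14),
               tolerance = 0.05)

  p <- c(3, 1, 4, 1, 5)
  expect_equal(resample_profile(p, n_grid = 5L), as.vector(scale(p)),
               tolerance = 1e-12)

  expect_error(resample_profile(rep(2, 8)), "constant")
  expect_error(resample_profile(c(1, 2)), "3 sections")
})

test_that("tip-third means cover the last ceiling(n/3) sections", {
  m15 <- make_mat(matrix(1:15, nrow = 1, byrow = TRUE), genes = "g")
  expect_equal(tip_third_mean(m15, "g"), mean(11:15))
  m14 <- make_mat(matrix(1:14, nrow = 1), genes = "g")
  expect_equal(tip_third_mean(m14, "g"), mean(10:14))
  mc <- make_mat(matrix(7, nrow = 1, ncol = 9), genes = "g")
  expect_equal(tip_third_mean(mc, "g"), 7)
  expect_error(tip_third_mean(m15, "nope"), "unknown gene")
})

test_that("C4 modules are anchored on markers and must rise base to tip", {
  sections <- sprintf("S%02d", 1:8)
  rising <- as.vector(scale(1:8)); rising <- rising / sqrt(sum(rising^2))
  rising2 <- as.vector(scale(c(1:7, 7.5))); rising2 <- rising2 / sqrt(sum(rising2^2))
  falling <- rev(rising)
  E <- cbind(turquoise = rising, blue = rising2, brown = falling)
  rownames(E) <- sections
  labels <- stats::setNames(rep(c("turquoise", "blue", "brown"), each = 10),
                            sprintf("M%02d", 1:30))
  part <- module_partition(labels, "M", eigengenes = E)
  markers <- list(M = list(PEPC = "M01", PPDK = "M02"))
  ps <- list(M = c("turquoise", "blue", "brown"))
  got <- identify_c4_modules(list(M = part), markers, ps)
  expect_setequal(got$M, c("turquoise", "blue"))   # blue via eigengene rule

  # marker-free PS module with low eigengene correlation is excluded
  ps2 <- list(M = c("blue", "brown"))
  markers2 <- list(M = list(PEPC = "M01"))
  got2 <- identify_c4_modules(list(M = part), markers2, ps2)
  expect_identical(got2$M, "blue")

  expect_error(identify_c4_modules(list(M = part),
                                   list(M = list(PEPC = "absent")), ps),
               "no marker gene")
})

test_that("candidates are classified into the three types by the rules", {
  fx <- candidate_fixture()
  tab <- classify_candidates(fx$c4_modules, fx$parts, fx$mats, fx$orth,
                             fx$diff, c3_code = "R")
  got <- stats::setNames(tab$type, tab$group_id)
  expect_identical(unname(got["og1"]), "unclassified")  # fold 1: conserved
  expect_identical(unname(got["og2"]), "I")             # folds 3.0 and 2.4
  expect_identical(unname(got["og3"]), "unclassified")  # min fold 1.49 < 1.5
  expect_identical(unname(got["og4"]), "II")            # reversed + 2x support
  expect_identical(unname(got["og5"]), "III")           # reference map-absent
  expect_identical(unname(got["og6"]), "untestable")    # filtered from matrix

  row2 <- tab[tab$group_id == "og2", ]
  expect_gte(row2$pattern_cor, 0.5)
  expect_equal(row2$min_fold, 2.4, tolerance = 1e-9)
  row4 <- tab[tab$group_id == "og4", ]
  expect_identical(row4$diff_support, 2L)
  expect_identical(row4$diff_direction, "higher_in_C4")
  expect_lt(row4$pattern_cor, 0.5)

  # each pool group receives exactly one verdict
  expect_false(anyDuplicated(tab$group_id) > 0)

  # uniform rescaling of all RPKM values changes nothing
  tab_scaled <- classify_candidates(fx$c4_modules, fx$parts,
                                    candidate_fixture(rpkm_scale = 3.7)$mats,
                                    fx$orth, fx$diff, c3_code = "R")
  expect_identical(tab_scaled$type, tab$type)
  expect_equal(tab_scaled$min_fold, tab$min_fold, tolerance = 1e-9)
})

test_that("type II requires agreeing directions in two comparisons", {
  fx <- candidate_fixture()
  # directions disagree: no type II
  fx$diff$S$direction["SR.turquoise"] <- "lower_in_C4"
  tab <- classify_candidates(fx$c4_modules, fx$parts, fx$mats, fx$orth,
                             fx$diff, c3_code = "R")
  expect_identical(tab$type[tab$group_id == "og4"], "unclassified")

  # only one comparison supports: no type II either
  fx2 <- candidate_fixture()
  fx2$diff$S$labels["og4"] <- "unassigned"
  tab2 <- classify_candidates(fx2$c4_modules, fx2$parts, fx2$mats, fx2$orth,
                              fx2$diff, c3_code = "R")
  expect_identical(tab2$type[tab2$group_id == "og4"], "unclassified")
})
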