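make_partition <- function(labels, species) {
  module_partition(labels, species)
}

simple_orth <- function(n, codes = c("M", "R")) {
  df <- data.frame(group_id = sprintf("og%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (sp in codes) df[[sp]] <- sprintf("%s%03d", sp, seq_len(n))
  orthologue_map(df, codes)
}

test_that("module overlap p-values match exact hypergeometric enumeration", {
  orth <- simple_orth(20)
  la <- stats::setNames(rep(c("turquoise", "blue"), c(5, 15)),
                        sprintf("M%03d", 1:20))
  lb <- stats::setNames(rep(c("turquoise", "blue"), c(5, 15)),
                        sprintf("R%03d", 1:20))
  ov <- fisher_overlap(make_partition(la, "M"), make_partition(lb, "R"), orth)
  row <- ov[ov$module_a == "M.turquoise" & ov$module_b == "R.turquoise", ]
  expect_identical(row$k, 5L)
  expect_equal(row$p_value, 1 / choose(20, 5))
  expect_equal(row$p_value, 6.449948e-05, tolerance = 1e-6)

  # zero overlap (disjoint modules, n_a + n_b <= N) gives p = 1
  r2 <- ov[ov$module_a == "M.turquoise" & ov$module_b == "R.blue", ]
  expect_identical(r2$k, 0L)
  expect_equal(r2$p_value, 1)
})

test_that("overlap p-values agree with the summation oracle on random tables", {
  set.seed(23)
  for (rep in 1:20) {
    big_n <- sample(10:60, 1)
    n_a <- sample(1:big_n, 1)
    n_b <- sample(1:big_n, 1)
    k <- sample(max(0, n_a + n_b - big_n):min(n_a, n_b), 1)
    p <- stats::phyper(k - 1, n_a, big_n - n_a, n_b, lower.tail = FALSE)
    expect_equal(p, oracle_hyper_tail(k, n_a, n_b, big_n), tolerance = 1e-12)
  }
})

test_that("overlap results are invariant to gene relabelling and consistent", {
  set.seed(29)
  n <- 60
  orth <- simple_orth(n)
  la <- stats::setNames(sample(c("turquoise", "blue", UNASSIGNED_LABEL), n,
                               replace = TRUE), sprintf("M%03d", 1:n))
  lb <- stats::setNames(sample(c("turquoise", "brown"), n, replace = TRUE),
                        sprintf("R%03d", 1:n))
  ov <- fisher_overlap(make_partition(la, "M"), make_partition(lb, "R"), orth,
                       include_grey = TRUE)

  # permuting which gene carries which label leaves the p-values unchanged
  perm <- sample(n)
  la_p <- stats::setNames(unname(la)[perm], sprintf("M%03d", 1:n))
  lb_p <- stats::setNames(unname(lb)[perm], sprintf("R%03d", 1:n))
  ov_p <- fisher_overlap(make_partition(la_p, "M"), make_partition(lb_p, "R"),
                         orth, include_grey = TRUE)
  expect_equal(sort(ov$p_value), sort(ov_p$p_value))

  # overlap counts for a fixed B module sum to that module's size
  for (mb in unique(ov$module_b)) {
    sub <- ov[ov$module_b == mb, ]
    expect_identical(sum(sub$k), sub$n_b[1L])
  }

  # empty universe errors
  orth_bad <- orth
  orth_bad$R <- paste0("x", orth_bad$R)
  expect_error(fisher_overlap(make_partition(la, "M"),
                              make_partition(lb, "R"),
                              orthologue_map(orth_bad, c("M", "R"))),
               "universe")
})

test_that("bin enrichment combines hypergeometric tails with BH adjustment", {
  labels <- stats::setNames(rep(c("turquoise", "blue", UNASSIGNED_LABEL),
                                c(20, 20, 60)), sprintf("g%03d", 1:100))
  part <- make_partition(labels, "M")
  # one bin exactly equals the turquoise module; another is spread uniformly
  ann <- rbind(data.frame(gene_id = sprintf("g%03d", 1:20), bin = "PS"),
               data.frame(gene_id = sprintf("g%03d", seq(1, 100, by = 5)),
                          bin = "transport"))
  enr <- bin_enrichment(part, ann)
  ps_turq <- enr[enr$module == "turquoise" & enr$bin == "PS", ]
  expect_equal(ps_turq$k, 20L)
  expect_equal(ps_turq$p_value, min(enr$p_value))
  expect_equal(ps_turq$p_value,
               oracle_hyper_tail(20, 20, 20, 100), tolerance = 1e-12)
  expect_equal(enr$q_value, oracle_bh(enr$p_value))
  expect_gte(min(enr$q_value), min(enr$p_value))

  spread <- enr[enr$bin == "transport", ]
  expect_true(all(spread$q_value > 0.5))
})

test_that("photosynthesis modules are flagged by q-value", {
  enr <- data.frame(module = c("turquoise", "blue", "brown"),
                    bin = c("PS", "PS", "transport"),
                    q_value = c(0.001, 0.2, 0.001))
  expect_identical(flag_ps_modules(enr, "PS"), "turquoise")
  expect_identical(flag_ps_modules(enr, "PS", q_cut = 0.5),
                   c("blue", "turquoise"))
})

test_that("a planted PS-rich module is the only one flagged", {
  cfg <- simulation_config(n_genes = 600L, n_type1 = 0L, n_type2 = 0L,
                           n_type3 = 0L, diff_module_size = 0L,
                           diff_companion_size = 0L, seed = 19L)
  ds <- generate_dataset(cfg)
  truth <- ds$truth$modules$G
  labels <- stats::setNames(rep(UNASSIGNED_LABEL,
                                nrow(ds$expression$G$values)),
                            rownames(ds$expression$G$values))
  labels[names(truth)] <- truth
  part <- make_partition(labels, "G")
  enr <- bin_enrichment(part, ds$annotation)
  expect_identical(flag_ps_modules(enr, "PS"), "mod1")
})
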