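# Synthetic multi-species leaf-gradient expression data with planted ground
# truth: co-expression modules driven by smooth latent profiles over relative
# leaf position, classic C4 markers inside the rising module, planted type
# I/II/III candidate genes, a planted differential co-expression block, and
# the orthologue map / marker / annotation side tables the pipeline consumes.
#
# Latent profiles are parametric curves over relative position t in [0, 1]
# (0 = leaf base, 1 = tip): a logistic rise (the C4/photosynthesis pattern),
# a reversed logistic fall, and Gaussian transients at staggered centres. The
# default five module shapes were chosen so that no pair exceeds |r| ~ 0.6 at
# leaf-gradient section counts, keeping planted modules separable in an
# unsigned network. Noise is multiplicative lognormal on RPKM, i.e. additive
# Gaussian on the log2 scale, matching the log2(x+1) transform used upstream.

LATENT_SHAPES <- list(
  rising     = function(t) stats::plogis((t - 0.60) / 0.10),
  falling    = function(t) stats::plogis((0.40 - t) / 0.10),
  bump_early = function(t) exp(-(t - 0.12)^2 / (2 * 0.08^2)),
  bump_mid1  = function(t) exp(-(t - 0.32)^2 / (2 * 0.08^2)),
  bump_mid2  = function(t) exp(-(t - 0.52)^2 / (2 * 0.08^2)),
  bump_late  = function(t) exp(-(t - 0.72)^2 / (2 * 0.08^2))
)

# Shape given to type II genes in the C3 reference: the reversed gradient,
# which correlates strongly negatively with the rising C4 pattern (well below
# the 0.5 pattern threshold) and coincides with no planted module latent.
TYPE2_ALT_SHAPES <- c("falling")

latent_profile <- function(shape, n_sections) {
  f <- LATENT_SHAPES[[shape]]
  if (is.null(f)) stop(sprintf("unknown latent shape '%s'", shape))
  as.vector(scale(f(seq(0, 1, length.out = n_sections))))
}

# standardized random smooth curve (low-order cosine series); used for the
# reference profiles of planted differential-module genes
random_smooth_profile <- function(n_sections) {
  t <- seq(0, 1, length.out = n_sections)
  z <- stats::rnorm(3L)
  p <- z[1L] * cos(pi * t) + z[2L] * cos(2 * pi * t) + z[3L] * cos(3 * pi * t)
  if (stats::sd(p) == 0) p <- cos(pi * t)
  as.vector(scale(p))
}

#' Simulation configuration for synthetic leaf-gradient data
#'
#' Defaults encode the four-species design: three C4 species (M, G, S) with
#' 15, 10 and 13 sections and a C3 reference (R) with 11 sections; 2000
#' orthologue groups per species; five planted 100-gene modules (one rising
#' "C4" module carrying the six classic markers, four transients) at noise sd
#' 0.3 on the log2 scale; 20 type I (2-fold reference reduction), 20 type II
#' and 10 type III planted candidates inside the rising module; one 60-gene
#' planted differential block; and 90\% orthologue coverage for background
#' genes (planted genes are fully covered, modelling conserved photosynthesis
#' machinery).
#'
#' @param species Data frame with columns `code`, `n_sections`, `role`
#'   (`"C4"`/`"C3"`; exactly one C3 reference).
#' @param n_genes Number of orthologue groups.
#' @param modules Data frame with columns `name`, `size`, `shape`
#'   (names of `LATENT_SHAPES`), `noise_sd`. The first module is the rising
#'   C4 module hosting markers and candidates.
#' @param n_type1,type1_fold Planted type I gene count and the factor by which
#'   their reference expression is divided (must exceed 1).
#' @param n_type2 Planted type II count (reference latent swapped to the
#'   falling shape, i.e. the expression trend reverses in the reference).
#' @param n_type3 Planted type III count (reference orthologue absent).
#' @param diff_module_size Size of the planted differential block of the
#'   first C4 species; its genes follow the rising latent in that species
#'   only and are plain noise (uncorrelated) in the reference and the other
#'   C4 species, so they are differentially co-expressed in exactly one
#'   comparison without entering the candidate pool. 0 disables it.
#' @param diff_companion_size Size of the analogous differential block planted
#'   for each remaining C4 species. These blocks guarantee that every
#'   C4-vs-reference comparison carries a differential module large enough to
#'   survive the 30-gene floor, inside which the planted type II genes ride.
#' @param orth_coverage Probability that a background gene is present in a
#'   given species.
#' @param ps_rate_module,ps_rate_background Probability of a "PS" annotation
#'   for rising-module genes and for all other genes.
#' @param base_mu,base_sd Log2 mean and sd of planted genes' base expression.
#' @param background_mu,background_sd Same for background genes.
#' @param species_jitter_sd Log2 sd of the per-species jitter on base
#'   expression (kept small: orthologues have conserved expression levels
#'   unless planted otherwise).
#' @param plant_outlier_section If TRUE, section 1 of every C4 species is
#'   replaced by expression unrelated to gene identity, emulating a basal
#'   outlier section.
#' @param seed Integer seed fixing the dataset bit-exactly.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    species = data.frame(code = c("M", "G", "S", "R"),
                         n_sections = c(15L, 10L, 13L, 11L),
                         role = c("C4", "C4", "C4", "C3"),
                         stringsAsFactors = FALSE),
    n_genes = 2000L,
    modules = data.frame(name = paste0("mod", 1:5),
                         size = 100L,
                         shape = c("rising", "bump_early", "bump_mid1",
                                   "bump_mid2", "bump_late"),
                         noise_sd = 0.3,
                         stringsAsFactors = FALSE),
    n_type1 = 20L, type1_fold = 2,
    n_type2 = 20L,
    n_type3 = 10L,
    diff_module_size = 60L,
    diff_companion_size = 40L,
    orth_coverage = 0.9,
    ps_rate_module = 0.8, ps_rate_background = 0.05,
    base_mu = 5, base_sd = 1,
    background_mu = 3, background_sd = 2,
    species_jitter_sd = 0.1,
    plant_outlier_section = FALSE,
    seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("code", "n_sections", "role") %in% colnames(species)),
            sum(species$role == "C3") == 1L,
            all(species$n_sections >= 3L),
            is.data.frame(modules),
            all(c("name", "size", "shape", "noise_sd") %in% colnames(modules)),
            all(modules$size >= 2L), all(modules$noise_sd > 0),
            all(modules$shape %in% names(LATENT_SHAPES)),
            n_type1 >= 0L, n_type2 >= 0L, n_type3 >= 0L, type1_fold > 1,
            diff_module_size >= 0L, diff_companion_size >= 0L,
            orth_coverage > 0, orth_coverage <= 1)
  n_candidates <- 6L + n_type1 + n_type2 + n_type3
  if (nrow(modules) < 1L || modules$size[1L] < n_candidates) {
    stop("first (rising) module too small for markers plus planted candidates")
  }
  n_c4 <- sum(species$role == "C4")
  total_diff <- if (n_c4 > 0L) {
    diff_module_size + max(0L, n_c4 - 1L) * diff_companion_size
  } else 0L
  if (sum(modules$size) + total_diff > n_genes) {
    stop("planted module sizes exceed n_genes")
  }
  structure(list(species = species, n_genes = as.integer(n_genes),
                 modules = modules, n_type1 = as.integer(n_type1),
                 type1_fold = type1_fold, n_type2 = as.integer(n_type2),
                 n_type3 = as.integer(n_type3),
                 diff_module_size = as.integer(diff_module_size),
                 diff_companion_size = as.integer(diff_companion_size),
                 orth_coverage = orth_coverage,
                 ps_rate_module = ps_rate_module,
                 ps_rate_background = ps_rate_background,
                 base_mu = base_mu, base_sd = base_sd,
                 background_mu = background_mu, background_sd = background_sd,
                 species_jitter_sd = species_jitter_sd,
                 plant_outlier_section = isTRUE(plant_outlier_section),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic multi-species leaf-gradient dataset
#'
#' Draws per-species expression matrices, the orthologue map, the marker set,
#' the annotation table and the ground-truth tables from a
#' [simulation_config()]. A gene's log2 expression is its group-level base
#' level plus a small per-species jitter, plus its module's standardized
#' latent profile (scaled by a per-group amplitude near 1), plus section-wise
#' Gaussian noise; RPKM is 2 to that power. Planted candidates deviate in the
#' C3 reference only: type I keep the rising pattern at a `type1_fold`-fold
#' lower level, type II follow a fixed alternative latent shape, type III are
#' absent from the reference matrix and orthologue map.
#'
#' @param cfg A `simulation_config`.
#' @return List with `expression` (named list of `expression_matrix`),
#'   `orthologues` (`orthologue_map`), `markers`, `annotation` (data frame
#'   `gene_id`/`bin`), `truth` (planted module labels per species, candidate
#'   table, differential gene sets) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  sp_codes <- cfg$species$code
  c3 <- cfg$species$code[cfg$species$role == "C3"]
  c4_codes <- setdiff(sp_codes, c3)

  group_id <- sprintf("og%05d", seq_len(n))
  gene_of <- function(sp) sprintf("%s%05d", sp, seq_len(n))

  # gene roles ------------------------------------------------------------
  mod_label <- rep(NA_character_, n)
  pos <- 1L
  for (i in seq_len(nrow(cfg$modules))) {
    mod_label[seq.int(pos, pos + cfg$modules$size[i] - 1L)] <- cfg$modules$name[i]
    pos <- pos + cfg$modules$size[i]
  }
  diff_home <- rep(NA_character_, n)
  for (k in seq_along(c4_codes)) {
    sz <- if (k == 1L) cfg$diff_module_size else cfg$diff_companion_size
    if (sz > 0L) {
      diff_home[seq.int(pos, pos + sz - 1L)] <- c4_codes[k]
      pos <- pos + sz
    }
  }
  diff_idx <- which(!is.na(diff_home))
  background <- seq_len(n) >= pos & is.na(diff_home)

  marker_idx <- seq_len(6L)
  type1_idx <- seq.int(7L, length.out = cfg$n_type1)
  type2_idx <- seq.int(7L + cfg$n_type1, length.out = cfg$n_type2)
  type3_idx <- seq.int(7L + cfg$n_type1 + cfg$n_type2, length.out = cfg$n_type3)

  # base expression and amplitudes ----------------------------------------
  mu <- ifelse(background,
               stats::rnorm(n, cfg$background_mu, cfg$background_sd),
               stats::rnorm(n, cfg$base_mu, cfg$base_sd))
  amp <- stats::runif(n, 0.9, 1.1)

  # presence: planted genes fully covered; background genes dropped out
  present <- matrix(TRUE, nrow = n, ncol = length(sp_codes),
                    dimnames = list(group_id, sp_codes))
  present[background, ] <- matrix(
    stats::runif(sum(background) * length(sp_codes)) < cfg$orth_coverage,
    ncol = length(sp_codes))
  none <- rowSums(present) == 0L
  present[none, 1L] <- TRUE
  present[type3_idx, c3] <- FALSE

  type2_alt <- rep(TYPE2_ALT_SHAPES, length.out = cfg$n_type2)

  # expression matrices ----------------------------------------------------
  expression <- list()
  for (si in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$code[si]
    ns <- cfg$species$n_sections[si]
    lat <- vapply(stats::setNames(nm = names(LATENT_SHAPES)),
                  latent_profile, numeric(ns), n_sections = ns)
    idx <- which(present[, sp])
    logx <- matrix(0, nrow = length(idx), ncol = ns)
    jitter <- stats::rnorm(length(idx), 0, cfg$species_jitter_sd)
    for (r in seq_along(idx)) {
      g <- idx[r]
      base <- mu[g] + jitter[r]
      if (g %in% type1_idx && sp == c3) base <- base - log2(cfg$type1_fold)
      prof <- rep(0, ns)
      noise_sd <- cfg$modules$noise_sd[1L]
      if (!is.na(mod_label[g])) {
        mi <- match(mod_label[g], cfg$modules$name)
        noise_sd <- cfg$modules$noise_sd[mi]
        shape <- cfg$modules$shape[mi]
        if (sp == c3 && g %in% type2_idx) {
          shape <- type2_alt[match(g, type2_idx)]
        }
        prof <- amp[g] * lat[, shape]
      } else if (!is.na(diff_home[g])) {
        if (sp == diff_home[g]) prof <- amp[g] * lat[, cfg$modules$shape[1L]]
      }
      logx[r, ] <- base + prof + stats::rnorm(ns, 0, noise_sd)
    }
    vals <- 2^logx
    if (cfg$plant_outlier_section && cfg$species$role[si] == "C4") {
      vals[, 1L] <- 2^stats::rnorm(length(idx), mean(mu), 2)
    }
    dimnames(vals) <- list(gene_of(sp)[idx],
                           paste0("S", sprintf("%02d", seq_len(ns))))
    expression[[sp]] <- expression_matrix(vals, sp)
  }

  # orthologue map ---------------------------------------------------------
  orth_df <- data.frame(group_id = group_id, stringsAsFactors = FALSE)
  for (sp in sp_codes) {
    v <- gene_of(sp)
    v[!present[, sp]] <- NA_character_
    orth_df[[sp]] <- v
  }
  orth <- orthologue_map(orth_df, sp_codes)

  # markers -----------------------------------------------------------------
  markers <- list()
  for (sp in sp_codes) {
    markers[[sp]] <- stats::setNames(
      as.list(gene_of(sp)[marker_idx]), C4_MARKER_NAMES)
  }

  # annotation --------------------------------------------------------------
  rising_name <- cfg$modules$name[1L]
  other_bins <- c("protein", "transport", "major CHO metabolism",
                  "RNA regulation", "not assigned")
  ann <- list()
  for (sp in sp_codes) {
    ids <- gene_of(sp)[present[, sp]]
    gidx <- which(present[, sp])
    in_rising <- !is.na(mod_label[gidx]) & mod_label[gidx] == rising_name
    rate <- ifelse(in_rising, cfg$ps_rate_module, cfg$ps_rate_background)
    is_ps <- stats::runif(length(ids)) < rate
    ann[[sp]] <- data.frame(
      gene_id = ids,
      bin = ifelse(is_ps, "PS", sample(other_bins, length(ids), replace = TRUE)),
      stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL

  # ground truth ------------------------------------------------------------
  truth_modules <- list()
  for (sp in sp_codes) {
    lab <- mod_label
    home <- !is.na(diff_home) & diff_home == sp
    if (any(home)) lab[home] <- cfg$modules$name[1L]
    keep <- !is.na(lab) & present[, sp]
    if (sp == c3) {
      keep[type2_idx] <- FALSE   # reference latent swapped: not module members
    }
    truth_modules[[sp]] <- stats::setNames(lab[keep], gene_of(sp)[keep])
  }
  cand <- data.frame(
    group_id = group_id[c(type1_idx, type2_idx, type3_idx)],
    type = rep(c("I", "II", "III"),
               c(cfg$n_type1, cfg$n_type2, cfg$n_type3)),
    stringsAsFactors = FALSE)
  diff_ids <- group_id[c(diff_idx, type2_idx)]
  diff_truth <- data.frame(
    group_id = diff_ids,
    set = c(rep("diff_plant", length(diff_idx)), rep("type2", cfg$n_type2)),
    comparison = c(diff_home[diff_idx], rep("all", cfg$n_type2)),
    direction = rep("higher_in_C4", length(diff_ids)),
    stringsAsFactors = FALSE)

  list(expression = expression, orthologues = orth, markers = markers,
       annotation = annotation,
       truth = list(modules = truth_modules, candidates = cand,
                    diff = diff_truth, c3_code = c3, c4_codes = c4_codes),
       config = cfg)
}

#' Generate a matched null dataset
#'
#' Produces the dataset of `cfg` with the named structure destroyed:
#' `"shuffle_sections"` permutes every gene's section values independently
#' (destroying all co-expression while preserving marginal expression
#' levels); `"shuffle_orthologues"` permutes each species' gene assignments
#' across orthologue groups (destroying cross-species correspondence while
#' preserving within-species networks). Used for type-I-error control of the
#' overlap and differential co-expression stages.
#'
#' @param cfg A `simulation_config`.
#' @param mode `"shuffle_sections"` or `"shuffle_orthologues"`.
#' @return Same structure as [generate_dataset()]; the planted truth no
#'   longer applies (attribute `null_mode` records the mode).
#' @export
null_dataset <- function(cfg, mode = c("shuffle_sections", "shuffle_orthologues")) {
  mode <- match.arg(mode)
  ds <- generate_dataset(cfg)
  set.seed(cfg$seed + 77773L)
  if (mode == "shuffle_sections") {
    for (sp in names(ds$expression)) {
      v <- ds$expression[[sp]]$values
      for (r in seq_len(nrow(v))) v[r, ] <- v[r, sample.int(ncol(v))]
      ds$expression[[sp]] <- expression_matrix(v, sp)
    }
  } else {
    orth <- as.data.frame(ds$orthologues)
    for (sp in setdiff(colnames(orth), "group_id")) {
      orth[[sp]] <- orth[[sp]][sample.int(nrow(orth))]
    }
    ds$orthologues <- orthologue_map(orth, setdiff(colnames(orth), "group_id"))
  }
  attr(ds, "null_mode") <- mode
  ds
}
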