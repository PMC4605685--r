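# C4 candidate identification: anchoring C4 modules on the classic shuttle
# genes, and classifying orthologue groups into type I (level-shifted in
# rice), type II (pattern-changed in rice, with differential co-expression
# support) and type III (orthologue absent in rice). Because species have
# different section counts, expression patterns are compared on a common grid
# of relative leaf positions.

#' Resample a section profile onto a relative-position grid
#'
#' Standardizes the profile (mean 0, sd 1) and linearly interpolates it onto
#' `n_grid` equally spaced relative positions in \[0, 1\] (0 = leaf base,
#' 1 = tip), making profiles from species with different section counts
#' directly comparable.
#'
#' @param profile Numeric vector over at least 3 ordered sections.
#' @param n_grid Number of grid points (default 20).
#' @return Numeric vector of length `n_grid`.
#' @export
resample_profile <- function(profile, n_grid = 20L) {
  n <- length(profile)
  if (n < 3L) stop("a profile needs at least 3 sections")
  s <- stats::sd(profile)
  if (!is.finite(s) || s == 0) stop("constant profile cannot be standardized")
  z <- (profile - mean(profile)) / s
  stats::approx(x = seq(0, 1, length.out = n), y = z,
                xout = seq(0, 1, length.out = n_grid))$y
}

#' Identify C4 modules from classic marker genes
#'
#' Per C4 species, the C4 modules are the photosynthesis-enriched modules that
#' either (a) contain at least one classic C4 marker gene, or (b) have an
#' eigengene correlating at least `ref_cor` with the eigengene of some
#' marker-containing module; additionally the module eigengene must increase
#' from base to tip (positive Spearman correlation with the section index),
#' matching the expression profile of the C4 shuttle.
#'
#' @param parts Named list (by species code) of `module_partition`s with
#'   eigengenes, for the C4 species.
#' @param markers Marker set as returned by [read_marker_set()]:
#'   `markers[[species]][[marker]]` = gene ids.
#' @param ps_modules Named list (by species code) of photosynthesis-flagged
#'   module labels (see [flag_ps_modules()]).
#' @param ref_cor Eigengene-correlation threshold for rule (b) (default 0.9).
#' @return Named list (by species code) of C4 module label vectors.
#' @export
identify_c4_modules <- function(parts, markers, ps_modules, ref_cor = 0.9) {
  stopifnot(is.list(parts), length(parts) > 0L)
  unresolved <- character(0)
  out <- list()
  for (sp in names(parts)) {
    part <- parts[[sp]]
    if (is.null(part$eigengenes)) {
      stop(sprintf("partition for species '%s' lacks eigengenes", sp))
    }
    mk_ids <- unlist(markers[[sp]], use.names = FALSE)
    mk_in <- mk_ids[mk_ids %in% names(part$labels)]
    mk_mods <- setdiff(unique(part$labels[mk_in]), UNASSIGNED_LABEL)
    if (length(mk_mods) == 0L) {
      unresolved <- c(unresolved, paste0(sp, ":",
                                         paste(mk_ids, collapse = ",")))
      out[[sp]] <- character(0)
      next
    }
    cand <- ps_modules[[sp]] %||% character(0)
    keep <- character(0)
    for (m in cand) {
      if (!m %in% colnames(part$eigengenes)) next
      e <- part$eigengenes[, m]
      rising <- suppressWarnings(
        stats::cor(e, seq_along(e), method = "spearman")) > 0
      if (is.na(rising) || !rising) next
      anchored <- m %in% mk_mods ||
        max(vapply(mk_mods, function(mm) {
          suppressWarnings(stats::cor(e, part$eigengenes[, mm]))
        }, numeric(1L)), na.rm = TRUE) >= ref_cor
      if (anchored) keep <- c(keep, m)
    }
    out[[sp]] <- keep
  }
  if (length(unresolved) == length(parts)) {
    stop(sprintf("no marker gene found in any module (%s)",
                 paste(unresolved, collapse = "; ")))
  }
  out
}

#' Mean expression over the tip third of the gradient
#'
#' Mean untransformed RPKM over the last `ceiling(n_sections / 3)` sections
#' (the photosynthetically mature tip third of the leaf).
#'
#' @param mat An `expression_matrix`.
#' @param gene Gene id.
#' @return A single non-negative number.
#' @export
tip_third_mean <- function(mat, gene) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!gene %in% gene_ids(mat)) stop(sprintf("unknown gene '%s'", gene))
  n <- ncol(mat$values)
  k <- ceiling(n / 3)
  mean(mat$values[gene, seq.int(n - k + 1L, n)])
}

#' Classify C4 candidate genes into types I, II and III
#'
#' The candidate pool consists of orthologue groups whose gene lies in a C4
#' module in at least two C4 species. Pool members are then classified by
#' comparison with the C3 reference (rice):
#' * **type III** -- the orthologue is present in all three C4 species but
#'   absent from the reference (map absence);
#' * **type I** -- the reference profile still follows the C4 pattern
#'   (correlation with the C4 reference eigengene on the resampled grid at
#'   least `pattern_cut`) but its tip-third expression is at least `fold_cut`
#'   lower than in **each** supporting C4 species;
#' * **type II** -- the reference pattern differs (correlation below
#'   `pattern_cut`) **and** the group lies in a retained differential
#'   co-expression module in at least two of the three C4-vs-reference
#'   comparisons with the same direction.
#'
#' Pool members matching no rule are reported `"unclassified"` with a reason;
#' members whose reference gene is in the orthologue map but missing from the
#' reference expression matrix (filtered out) are `"untestable"`. The C4
#' reference eigengene of a group is the module-size-weighted mean of the
#' supporting species' C4-module eigengenes on the resampled grid.
#'
#' @param c4_modules Named list (by C4 species code) of C4 module labels, from
#'   [identify_c4_modules()].
#' @param parts Named list of `module_partition`s with eigengenes for the C4
#'   species (a reference partition may be included; it is not needed for the
#'   rules).
#' @param mats Named list of post-filter `expression_matrix` objects for all
#'   species including the reference.
#' @param orth An `orthologue_map` covering all species.
#' @param diff_parts Named list (by C4 species code) of retained
#'   `diff_module_partition`s from the C4-vs-reference comparisons, keyed by
#'   orthologue group id.
#' @param c3_code Species code of the C3 reference (default `"R"`).
#' @param fold_cut Tip-third fold-change threshold for type I (default 1.5).
#' @param pattern_cut Pattern-correlation threshold separating types I and II
#'   (default 0.5).
#' @param n_grid Relative-position grid size (default 20).
#' @return Data frame of class `candidate_table`: one row per pool group with
#'   per-species gene ids, `type` (`"I"`, `"II"`, `"III"`, `"unclassified"`,
#'   `"untestable"`), supporting species, pattern correlation, minimum
#'   tip-third fold, differential support count and direction, and a reason
#'   string for unclassified rows.
#' @export
classify_candidates <- function(c4_modules, parts, mats, orth, diff_parts,
                                c3_code = "R", fold_cut = 1.5,
                                pattern_cut = 0.5, n_grid = 20L) {
  c4_codes <- names(c4_modules)
  stopifnot(length(c4_codes) >= 2L, c3_code %in% colnames(orth))
  for (sp in c4_codes) {
    if (!sp %in% names(parts)) stop(sprintf("missing partition for '%s'", sp))
    if (!sp %in% names(mats)) stop(sprintf("missing matrix for '%s'", sp))
  }
  if (!c3_code %in% names(mats)) stop("reference expression matrix required")

  # support: per group, the C4 species whose gene sits in a C4 module
  in_c4_module <- function(sp, gene) {
    !is.na(gene) && gene %in% names(parts[[sp]]$labels) &&
      parts[[sp]]$labels[gene] %in% c4_modules[[sp]]
  }
  support <- lapply(seq_len(nrow(orth)), function(i) {
    c4_codes[vapply(c4_codes, function(sp) in_c4_module(sp, orth[[sp]][i]),
                    logical(1L))]
  })
  pool <- which(vapply(support, length, integer(1L)) >= 2L)

  rows <- lapply(pool, function(i) {
    sup <- support[[i]]
    rice_gene <- orth[[c3_code]][i]
    row <- list(group_id = orth$group_id[i])
    for (sp in c(c4_codes, c3_code)) row[[paste0("gene_", sp)]] <- orth[[sp]][i]
    row$support <- paste(sup, collapse = ",")
    row$n_support <- length(sup)
    row$pattern_cor <- NA_real_
    row$min_fold <- NA_real_
    row$diff_support <- NA_integer_
    row$diff_direction <- NA_character_
    row$reason <- NA_character_

    if (is.na(rice_gene)) {
      all_c4 <- all(!is.na(unlist(lapply(c4_codes, function(sp) orth[[sp]][i]))))
      if (all_c4) {
        row$type <- "III"
        row$reason <- "map-absent"
      } else {
        row$type <- "unclassified"
        row$reason <- "reference absent but orthologue missing in some C4 species"
      }
      return(row)
    }
    if (!rice_gene %in% gene_ids(mats[[c3_code]])) {
      row$type <- "untestable"
      row$reason <- "reference orthologue filtered from expression matrix"
      return(row)
    }

    # C4 reference eigengene: size-weighted mean over supporting species
    grid <- matrix(NA_real_, nrow = n_grid, ncol = length(sup))
    w <- numeric(length(sup))
    for (j in seq_along(sup)) {
      sp <- sup[j]
      g <- orth[[sp]][i]
      mod <- parts[[sp]]$labels[g]
      grid[, j] <- resample_profile(parts[[sp]]$eigengenes[, mod], n_grid)
      w[j] <- sum(parts[[sp]]$labels == mod)
    }
    ref <- as.vector(grid %*% (w / sum(w)))
    rice_prof <- log2(mats[[c3_code]]$values[rice_gene, ] + 1)
    rice_rs <- tryCatch(resample_profile(rice_prof, n_grid),
                        error = function(e) NULL)
    if (is.null(rice_rs)) {
      row$type <- "untestable"
      row$reason <- "constant reference profile"
      return(row)
    }
    row$pattern_cor <- suppressWarnings(stats::cor(rice_rs, ref))
    if (is.na(row$pattern_cor)) {
      row$type <- "untestable"
      row$reason <- "undefined pattern correlation"
      return(row)
    }

    if (row$pattern_cor >= pattern_cut) {
      rice_tip <- tip_third_mean(mats[[c3_code]], rice_gene)
      folds <- vapply(sup, function(sp) {
        tip <- tip_third_mean(mats[[sp]], orth[[sp]][i])
        if (rice_tip == 0) {
          if (tip > 0) Inf else NA_real_
        } else {
          tip / rice_tip
        }
      }, numeric(1L))
      row$min_fold <- if (all(is.na(folds))) NA_real_ else min(folds, na.rm = TRUE)
      if (!is.na(row$min_fold) && row$min_fold >= fold_cut) {
        row$type <- "I"
        return(row)
      }
      row$type <- "unclassified"
      row$reason <- "pattern conserved but tip-third fold below threshold"
      return(row)
    }

    # pattern changed: require differential co-expression support
    dirs <- character(0)
    for (sp in names(diff_parts)) {
      dp <- diff_parts[[sp]]
      gid <- orth$group_id[i]
      if (gid %in% names(dp$labels) && dp$labels[gid] != "unassigned") {
        dirs <- c(dirs, unname(dp$direction[dp$labels[gid]]))
      }
    }
    row$diff_support <- length(dirs)
    if (length(dirs) >= 2L) {
      tab <- sort(table(dirs), decreasing = TRUE)
      if (tab[1L] >= 2L) {
        row$diff_direction <- names(tab)[1L]
        row$type <- "II"
        return(row)
      }
    }
    row$type <- "unclassified"
    row$reason <- "pattern changed but differential co-expression support insufficient"
    row
  })

  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(group_id = character(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("candidate_table", "data.frame")
  attr(out, "c4_codes") <- c4_codes
  attr(out, "c3_code") <- c3_code
  out
}

#' Summarise a candidate table
#'
#' @param object A `candidate_table`.
#' @param ... Unused.
#' @return Data frame of counts per candidate type.
#' @export
summary.candidate_table <- function(object, ...) {
  tab <- table(factor(object$type,
                      levels = c("I", "II", "III", "unclassified", "untestable")))
  data.frame(type = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
}
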