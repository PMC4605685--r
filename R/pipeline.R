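# End-to-end pipeline driver: filtering -> outlier removal -> per-species
# co-expression networks -> enrichment and cross-species overlap ->
# C4-vs-reference differential co-expression -> candidate typing. Driven by a
# single YAML (or list) configuration; every stage writes its TSV outputs and
# all parameter values land in a run log. Outputs contain no timestamps, so a
# rerun with the same configuration is checksum-identical.

pipeline_defaults <- function() {
  list(
    filtering = list(rpkm_cut = 1, frac = 0.10, outlier_min_cor = 0.6,
                     drop_outliers = TRUE),
    network = list(transform = "log2p1", beta = as.list(SOFT_POWER_DEFAULTS),
                   min_module_size = 30L, merge_cor = 0.9,
                   cut_quantile = 0.99, core_frac = 0.97, min_gap = 0.15),
    enrichment = list(ps_bins = list("PS"), q_cut = 0.05),
    diffcoex = list(beta = 6L, delta = 0.7, frac_cut = 0.10, min_size = 30L),
    candidates = list(fold_cut = 1.5, pattern_cut = 0.5, ref_cor = 0.9,
                      n_grid = 20L)
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    cfg_args <- args[names(args) %in% names(formals(simulation_config))]
    ds <- generate_dataset(do.call(simulation_config, cfg_args))
    return(list(expression = ds$expression, orthologues = ds$orthologues,
                markers = ds$markers, annotation = ds$annotation,
                truth = ds$truth))
  }
  io <- config$io
  if (is.null(io)) stop("config needs an 'io' or 'synthetic' section")
  codes <- names(io$expression)
  expression <- lapply(stats::setNames(nm = codes), function(sp) {
    read_expression_table(io$expression[[sp]], sp)
  })
  list(expression = expression,
       orthologues = read_orthologue_map(io$orthologues, codes),
       markers = read_marker_set(io$markers),
       annotation = read_annotation_map(io$annotation),
       truth = NULL)
}

#' Run the comparative co-expression pipeline
#'
#' Executes all stages from one configuration: per-species low-expression
#' filtering and outlier-section removal, unsigned weighted network and
#' module detection with eigengene merging, functional-bin enrichment and
#' cross-species Fisher overlap, one differential co-expression comparison
#' per C4 species against the C3 reference, and candidate typing. All stage
#' tables, a parameter log and a summary report are written under `out_dir`.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Required: either `io` (paths: `expression` (named by species
#'   code), `orthologues`, `markers`, `annotation`) or `synthetic` (arguments
#'   for [simulation_config()]), plus `c3_reference` (species code of the C3
#'   reference). Optional sections `filtering`, `network`, `enrichment`,
#'   `diffcoex`, `candidates` override the documented defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `summary` (module counts per species,
#'   differential gene counts per comparison, candidate counts per type),
#'   `candidates` (the candidate table), `partitions`, `diff`, and `paths`
#'   of the written files.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  p <- merge_config(pipeline_defaults(), config[setdiff(names(config),
                                                        c("io", "synthetic",
                                                          "c3_reference"))])
  c3 <- config$c3_reference
  if (is.null(c3)) stop("reference C3 species required (config key c3_reference)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("c4coex pipeline run",
                 paste0("config: ", paste(utils::capture.output(utils::str(p)),
                                          collapse = " ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- stage("input", load_pipeline_inputs(config))
  codes <- names(inputs$expression)
  if (!c3 %in% codes) stop("reference C3 species required (not among inputs)")
  c4_codes <- setdiff(codes, c3)

  # --- preprocessing ------------------------------------------------------
  mats <- list()
  for (sp in codes) {
    m <- stage("filter", filter_low_expression(inputs$expression[[sp]],
                                               p$filtering$rpkm_cut,
                                               p$filtering$frac))
    out <- stage("outliers", detect_outlier_sections(m, p$filtering$outlier_min_cor))
    if (isTRUE(p$filtering$drop_outliers) && length(out$outliers) > 0L) {
      log_lines <- c(log_lines, sprintf("%s: dropped outlier section(s) %s",
                                        sp, paste(out$outliers, collapse = ",")))
      m <- stage("outliers", drop_sections(m, out$outliers))
    }
    mats[[sp]] <- m
  }

  # --- per-species networks ----------------------------------------------
  parts <- list()
  enrich <- list()
  ps_mods <- list()
  for (sp in codes) {
    beta <- p$network$beta[[sp]] %||% SOFT_POWER_DEFAULTS[[sp]] %||% 6L
    cr <- stage("network", build_correlation(mats[[sp]], p$network$transform))
    adj <- soft_threshold(cr, beta)
    dis <- 1 - compute_tom(adj)
    part <- stage("modules",
                  detect_modules(dis, p$network$min_module_size, sp,
                                 p$network$cut_quantile, p$network$core_frac,
                                 p$network$min_gap))
    part <- add_module_eigengenes(part, mats[[sp]], p$network$transform)
    part <- merge_modules(part, mats[[sp]], p$network$merge_cor,
                          p$network$transform)
    parts[[sp]] <- part
    enrich[[sp]] <- stage("enrichment", bin_enrichment(part, inputs$annotation))
    ps_mods[[sp]] <- flag_ps_modules(enrich[[sp]],
                                     unlist(p$enrichment$ps_bins),
                                     p$enrichment$q_cut)
    write_table(data.frame(gene_id = names(part$labels),
                           module = unname(part$labels),
                           stringsAsFactors = FALSE),
                file.path(out_dir, sprintf("modules_%s.tsv", sp)))
    if (!is.null(part$eigengenes)) {
      write_table(data.frame(section = rownames(part$eigengenes),
                             part$eigengenes, check.names = FALSE),
                  file.path(out_dir, sprintf("eigengenes_%s.tsv", sp)))
    }
    write_table(enrich[[sp]], file.path(out_dir, sprintf("enrichment_%s.tsv", sp)))
  }

  # --- cross-species overlaps --------------------------------------------
  overlaps <- list()
  for (sp in c4_codes) {
    ov <- stage("overlap", fisher_overlap(parts[[sp]], parts[[c3]],
                                          inputs$orthologues))
    overlaps[[sp]] <- ov
    write_table(ov, file.path(out_dir, sprintf("overlap_%s_vs_%s.tsv", sp, c3)))
  }

  # --- differential co-expression ----------------------------------------
  diff_parts <- list()
  diff_counts <- integer(0)
  for (sp in c4_codes) {
    ga <- inputs$orthologues[[sp]]
    gb <- inputs$orthologues[[c3]]
    shared <- !is.na(ga) & !is.na(gb) &
      ga %in% gene_ids(mats[[sp]]) & gb %in% gene_ids(mats[[c3]])
    gids <- inputs$orthologues$group_id[shared]
    sub_a <- expression_matrix(
      `rownames<-`(mats[[sp]]$values[ga[shared], , drop = FALSE], gids), sp)
    sub_b <- expression_matrix(
      `rownames<-`(mats[[c3]]$values[gb[shared], , drop = FALSE], gids), c3)
    keep_a <- apply(log2(sub_a$values + 1), 1L, stats::sd) > 0
    keep_b <- apply(log2(sub_b$values + 1), 1L, stats::sd) > 0
    gids <- gids[keep_a & keep_b]
    cor_a <- build_correlation(
      expression_matrix(sub_a$values[gids, , drop = FALSE], sp),
      p$network$transform)
    cor_b <- build_correlation(
      expression_matrix(sub_b$values[gids, , drop = FALSE], c3),
      p$network$transform)
    dis <- stage("diffcoex", diff_dissimilarity(cor_a, cor_b, p$diffcoex$beta))
    dp <- stage("diffcoex",
                detect_diff_modules(dis, cor_a, cor_b, p$diffcoex$min_size,
                                    pair = c(sp, c3),
                                    cut_quantile = p$network$cut_quantile,
                                    core_frac = p$network$core_frac,
                                    min_gap = p$network$min_gap))
    dp <- filter_diff_modules(dp, cor_a, cor_b, p$diffcoex$delta,
                              p$diffcoex$frac_cut, p$diffcoex$min_size)
    diff_parts[[sp]] <- dp
    diff_counts[sp] <- sum(dp$labels != "unassigned")
    assigned <- dp$labels != "unassigned"
    write_table(data.frame(comparison = rep(paste0(sp, "_vs_", c3), sum(assigned)),
                           module = unname(dp$labels[assigned]),
                           group_id = names(dp$labels)[assigned],
                           direction = unname(dp$direction[dp$labels[assigned]]),
                           qualifying_pair_fraction =
                             unname(dp$qualifying_fraction[dp$labels[assigned]]),
                           stringsAsFactors = FALSE),
                file.path(out_dir, sprintf("diff_modules_%s_vs_%s.tsv", sp, c3)))
  }

  # --- candidates ---------------------------------------------------------
  c4_modules <- stage("c4_modules",
                      identify_c4_modules(parts[c4_codes], inputs$markers,
                                          ps_mods, p$candidates$ref_cor))
  candidates <- stage("candidates",
                      classify_candidates(c4_modules, parts, mats,
                                          inputs$orthologues, diff_parts,
                                          c3_code = c3,
                                          fold_cut = p$candidates$fold_cut,
                                          pattern_cut = p$candidates$pattern_cut,
                                          n_grid = p$candidates$n_grid))
  write_table(as.data.frame(candidates), file.path(out_dir, "candidates.tsv"))
  write_table(summary(candidates), file.path(out_dir, "candidate_summary.tsv"))

  # --- summary and log ----------------------------------------------------
  summary_df <- data.frame(
    species = codes,
    n_genes = vapply(codes, function(sp) nrow(mats[[sp]]$values), integer(1L)),
    n_sections = vapply(codes, function(sp) ncol(mats[[sp]]$values), integer(1L)),
    n_modules = vapply(codes, function(sp) length(module_sizes(parts[[sp]])),
                       integer(1L)),
    stringsAsFactors = FALSE)
  write_table(summary_df, file.path(out_dir, "summary_species.tsv"))
  diff_df <- data.frame(comparison = paste0(c4_codes, "_vs_", c3),
                        n_diff_genes = as.integer(diff_counts[c4_codes]),
                        stringsAsFactors = FALSE)
  write_table(diff_df, file.path(out_dir, "summary_diffcoex.tsv"))
  log_lines <- c(log_lines,
                 sprintf("comparisons: %d", length(c4_codes)),
                 sprintf("c4 modules: %s",
                         paste(vapply(names(c4_modules), function(sp)
                           paste0(sp, "=", paste(c4_modules[[sp]],
                                                 collapse = "+")),
                           character(1L)), collapse = "; ")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    summary = list(species = summary_df, diffcoex = diff_df,
                   candidates = summary(candidates),
                   n_comparisons = length(c4_codes)),
    candidates = candidates, partitions = parts, diff = diff_parts,
    c4_modules = c4_modules, enrichment = enrich, overlaps = overlaps,
    mats = mats, truth = inputs$truth,
    paths = list.files(out_dir, full.names = TRUE)))
}
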