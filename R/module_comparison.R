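# Cross-species module comparison on syntenic orthologue pairs, and
# functional-bin enrichment of modules. All tests are one-sided
# (over-representation) hypergeometric upper tails; enrichment p-values are
# Benjamini-Hochberg adjusted across all (module, bin) pairs of one species.
#
# The orthologue map constrains each group to at most one gene per species and
# each gene to one group, so every group contributes at most one orthologue
# pair to an overlap universe; no extra many-to-many reduction is needed.

#' Fisher overlap of modules between two species
#'
#' The universe is the set of orthologue groups whose genes are present (i.e.
#' survived filtering) in both partitions. For every pair of modules, the
#' overlap count is tested with the one-sided hypergeometric upper tail
#' `P(X >= k)`, equivalent to a one-sided Fisher exact test for
#' over-representation. "grey" is excluded from the tested module pairs by
#' default (unassigned genes still count in the universe).
#'
#' @param part_a,part_b `module_partition`s of two species.
#' @param orth An `orthologue_map` containing both species' columns.
#' @param include_grey Also test "grey" as a pseudo-module (default FALSE).
#' @return Data frame with one row per module pair: `module_a`, `module_b`,
#'   `k` (overlap), `n_a`, `n_b` (module sizes in orthologue-pair space),
#'   `universe`, `p_value`, `neg_log10_p`.
#' @export
fisher_overlap <- function(part_a, part_b, orth, include_grey = FALSE) {
  sp_a <- part_a$species_code
  sp_b <- part_b$species_code
  for (sp in c(sp_a, sp_b)) {
    if (!sp %in% colnames(orth)) {
      stop(sprintf("species '%s' not in orthologue map", sp))
    }
  }
  ga <- orth[[sp_a]]; gb <- orth[[sp_b]]
  shared <- !is.na(ga) & !is.na(gb) &
    ga %in% names(part_a$labels) & gb %in% names(part_b$labels)
  if (!any(shared)) stop("empty overlap universe: no shared orthologue pairs")
  la <- part_a$labels[ga[shared]]
  lb <- part_b$labels[gb[shared]]
  big_n <- sum(shared)
  mods_a <- sort(unique(la)); mods_b <- sort(unique(lb))
  if (!include_grey) {
    mods_a <- setdiff(mods_a, UNASSIGNED_LABEL)
    mods_b <- setdiff(mods_b, UNASSIGNED_LABEL)
  }
  res <- expand.grid(module_a = mods_a, module_b = mods_b,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$k <- mapply(function(a, b) sum(la == a & lb == b),
                  res$module_a, res$module_b)
  res$n_a <- as.integer(table(la)[res$module_a])
  res$n_b <- as.integer(table(lb)[res$module_b])
  res$universe <- big_n
  res$p_value <- stats::phyper(res$k - 1L, res$n_a, big_n - res$n_a, res$n_b,
                               lower.tail = FALSE)
  res$neg_log10_p <- -log10(res$p_value)
  res$module_a <- paste(sp_a, res$module_a, sep = ".")
  res$module_b <- paste(sp_b, res$module_b, sep = ".")
  res
}

#' Functional-bin enrichment of modules
#'
#' One hypergeometric upper-tail test per (module, bin) pair against the
#' universe of genes in the partition (i.e. the expressed, post-filter genes
#' of that species); q-values are Benjamini-Hochberg across all pairs.
#'
#' @param part A `module_partition`.
#' @param ann Annotation data frame with columns `gene_id`, `bin` (genes
#'   outside the partition are ignored; at least one annotated gene must
#'   remain).
#' @return Data frame with `module`, `bin`, `k` (annotated members),
#'   `module_size`, `bin_size`, `universe`, `p_value`, `q_value`,
#'   `neg_log10_q`.
#' @export
bin_enrichment <- function(part, ann) {
  stopifnot(is.data.frame(ann), all(c("gene_id", "bin") %in% colnames(ann)))
  ann <- ann[ann$gene_id %in% names(part$labels), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated gene in the partition universe")
  big_n <- length(part$labels)
  mods <- names(module_sizes(part))
  bins <- sort(unique(ann$bin))
  if (length(mods) == 0L) {
    return(data.frame(module = character(0), bin = character(0), k = integer(0),
                      module_size = integer(0), bin_size = integer(0),
                      universe = integer(0), p_value = numeric(0),
                      q_value = numeric(0), neg_log10_q = numeric(0)))
  }
  bin_genes <- split(ann$gene_id, ann$bin)
  res <- expand.grid(module = mods, bin = bins, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  res$k <- mapply(function(m, b) {
    sum(unique(bin_genes[[b]]) %in% module_members(part, m))
  }, res$module, res$bin)
  res$module_size <- as.integer(module_sizes(part)[res$module])
  res$bin_size <- vapply(res$bin, function(b) length(unique(bin_genes[[b]])),
                         integer(1L))
  res$universe <- big_n
  res$p_value <- stats::phyper(res$k - 1L, res$bin_size, big_n - res$bin_size,
                               res$module_size, lower.tail = FALSE)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$neg_log10_q <- -log10(res$q_value)
  res
}

#' Flag photosynthesis-enriched modules
#'
#' Modules significantly enriched (BH q-value at most `q_cut`) for any of the
#' listed photosynthesis bins.
#'
#' @param enrich Output of [bin_enrichment()].
#' @param ps_bins Bin labels counted as photosynthesis (e.g. `"PS"`).
#' @param q_cut q-value threshold (default 0.05).
#' @return Character vector of module labels.
#' @export
flag_ps_modules <- function(enrich, ps_bins, q_cut = 0.05) {
  stopifnot(is.data.frame(enrich))
  hit <- enrich$bin %in% ps_bins & enrich$q_value <= q_cut
  sort(unique(enrich$module[hit]))
}
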