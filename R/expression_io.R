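# Input/output for the tab-delimited tables consumed and produced by the
# pipeline. All files are UTF-8, tab-delimited, with a header row; lines
# starting with '#' are comments. Gene identifiers are opaque strings; species
# identity comes from file/column metadata, never from parsing the id.

#' Classic C4 shuttle marker names
#'
#' The six enzyme genes of the core C4 carbon shuttle used to anchor C4 modules:
#' carbonic anhydrase (CA), phosphoenolpyruvate carboxylase (PEPC),
#' NADP-malate dehydrogenase (NADP-MDH), NADP-malic enzyme (NADP-ME), pyruvate
#' orthophosphate dikinase (PPDK) and its regulatory protein (PPDK-RP).
#'
#' @export
C4_MARKER_NAMES <- c("CA", "PEPC", "NADP-MDH", "NADP-ME", "PPDK", "PPDK-RP")

#' Construct an expression matrix
#'
#' A per-species gene-by-section RPKM table. Sections are ordered along the
#' leaf developmental gradient: the first column is the leaf base (youngest
#' tissue), the last column the tip (oldest, photosynthetically mature).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), sections
#'   in columns (colnames = section labels, base first).
#' @param species_code Single-letter species label (e.g. "M", "G", "S", "R").
#' @return An object of class `expression_matrix` with fields `species_code`
#'   and `values`.
#' @export
expression_matrix <- function(values, species_code) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene ids (rownames) and section labels (colnames)")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate gene id '%s'", dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop(sprintf("duplicate section label '%s'", dup))
  }
  if (ncol(values) < 3L) stop("an expression matrix needs at least 3 sections")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative or non-finite value at gene '%s', section '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  }
  if (length(species_code) != 1L || !nzchar(species_code)) {
    stop("species_code must be a single non-empty label")
  }
  structure(list(species_code = species_code, values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: species %s, %d genes x %d sections (%s .. %s)\n",
              x$species_code, nrow(x$values), ncol(x$values),
              colnames(x$values)[1L], colnames(x$values)[ncol(x$values)]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param mat An `expression_matrix`.
#' @return Character vector of gene ids, in row order.
#' @export
gene_ids <- function(mat) rownames(mat$values)

#' Section labels of an expression matrix
#' @param mat An `expression_matrix`.
#' @return Character vector of section labels, base to tip.
#' @export
section_labels <- function(mat) colnames(mat$values)

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
}

#' Read a gene-by-section expression table
#'
#' Expects a tab-delimited file with a header row; the first column holds gene
#' ids, the remaining columns sections in base-to-tip order. The section order
#' of the file is preserved exactly. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param species_code Single-letter species label attached to the matrix.
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path, species_code) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 4L) stop("expression table needs a gene column plus at least 3 sections")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id '%s' in %s", ids[duplicated(ids)][1L], path))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', section '%s'",
                 vals[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  expression_matrix(num, species_code)
}

#' Read a cross-species syntenic orthologue map
#'
#' One row per orthologue group: a group id column followed by one column per
#' species holding that species' gene id. An empty cell or "NA" marks the
#' orthologue as absent in that species -- absences are preserved because they
#' later define type III candidates.
#'
#' @param path Path to the TSV file (columns: group_id, then one per species).
#' @param species_codes Species codes expected as columns, in order.
#' @return A data frame of class `orthologue_map` with columns `group_id` and
#'   one character column per species (`NA` = absent).
#' @export
read_orthologue_map <- function(path, species_codes) {
  df <- read_tsv_raw(path)
  if (!all(species_codes %in% colnames(df))) {
    miss <- setdiff(species_codes, colnames(df))
    stop(sprintf("orthologue map lacks species column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  out <- data.frame(group_id = df[[1L]], stringsAsFactors = FALSE)
  for (sp in species_codes) {
    v <- df[[sp]]
    v[v == "" | v == "NA"] <- NA_character_
    out[[sp]] <- v
  }
  orthologue_map(out, species_codes)
}

#' Construct/validate an orthologue map
#'
#' @param df Data frame with a `group_id` column and one character column per
#'   species; `NA` marks absence.
#' @param species_codes Species columns to validate.
#' @return The validated data frame with class `orthologue_map`.
#' @export
orthologue_map <- function(df, species_codes) {
  stopifnot(is.data.frame(df), "group_id" %in% colnames(df))
  if (anyDuplicated(df$group_id)) {
    stop(sprintf("duplicate orthologue group id '%s'",
                 df$group_id[duplicated(df$group_id)][1L]))
  }
  present <- rep(FALSE, nrow(df))
  for (sp in species_codes) {
    v <- df[[sp]]
    dup <- v[!is.na(v)][duplicated(v[!is.na(v)])]
    if (length(dup) > 0L) {
      stop(sprintf("gene '%s' appears in more than one orthologue group", dup[1L]))
    }
    present <- present | !is.na(v)
  }
  if (any(!present)) stop("orthologue group with no species present")
  attr(df, "species_codes") <- species_codes
  class(df) <- c("orthologue_map", "data.frame")
  df
}

#' Read a C4 marker-gene table
#'
#' Tab-delimited with columns `species`, `marker`, `gene_id`; one row per
#' (species, marker, gene) triple. Marker names must come from the fixed
#' six-name vocabulary ([C4_MARKER_NAMES]).
#'
#' @param path Path to the TSV file.
#' @return Nested list: `markers[[species]][[marker]]` = character vector of
#'   gene ids.
#' @export
read_marker_set <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("species", "marker", "gene_id")
  if (!all(need %in% colnames(df))) {
    stop("marker table needs columns species, marker, gene_id")
  }
  bad <- setdiff(unique(df$marker), C4_MARKER_NAMES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown marker name(s): %s", paste(bad, collapse = ", ")))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    sp <- df$species[i]; mk <- df$marker[i]
    out[[sp]][[mk]] <- c(out[[sp]][[mk]], df$gene_id[i])
  }
  out
}

#' Read a gene-to-functional-bin annotation table
#'
#' MapMan-style annotation: tab-delimited with columns `gene_id` and `bin`,
#' one row per gene-bin pair. Unannotated genes are simply absent.
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns `gene_id` and `bin`.
#' @export
read_annotation_map <- function(path) {
  df <- read_tsv_raw(path)
  if (!all(c("gene_id", "bin") %in% colnames(df))) {
    stop("annotation table needs columns gene_id, bin")
  }
  if (any(!nzchar(df$bin))) stop("empty bin label in annotation table")
  df[, c("gene_id", "bin")]
}

#' Write a result table as TSV
#'
#' Writes a data frame tab-delimited with a header. Floating-point columns are
#' rendered with 6 significant digits; re-reading with [read_result_table()]
#' yields identical content. Fields must be tab-free.
#'
#' @param records Data frame with a fixed column schema.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) {
      out[[j]] <- ifelse(is.na(v), NA_character_, formatC(signif(v, 6L), format = "g",
                                                          digits = 6L))
    } else {
      out[[j]] <- as.character(v)
    }
    has_tab <- grepl("\t", out[[j]], fixed = TRUE)
    if (any(has_tab, na.rm = TRUE)) {
      stop(sprintf("field containing a tab character in column '%s'",
                   colnames(out)[j]))
    }
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns type-converted (numeric where possible).
#' @export
read_result_table <- function(path) {
  df <- read_tsv_raw(path)
  for (j in seq_along(df)) {
    v <- df[[j]]
    suppressWarnings(num <- as.numeric(v))
    if (!any(is.na(num) & !is.na(v) & v != "NA")) df[[j]] <- num
  }
  df
}

#' Write an expression matrix as TSV
#'
#' @param mat An `expression_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(gene_id = gene_ids(mat), mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Write an orthologue map as TSV (absences rendered as "NA")
#'
#' @param orth An `orthologue_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orthologue_map <- function(orth, path) {
  write_table(as.data.frame(orth), path)
}
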