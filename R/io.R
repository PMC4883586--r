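#' Read a tab-separated feature-by-sample table
#'
#' Reads a TSV whose first column holds feature identifiers (taxa, KEGG
#' orthology groups, or compound IDs) and whose header row holds sample
#' identifiers. Duplicate feature IDs are allowed (metabolomic peak tables
#' may map several peaks to one compound; see
#' [collapse_duplicate_metabolites]).
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with feature IDs as row names and sample IDs as
#'   column names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table must have an ID column and at least one sample column: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample table as TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_label Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_label = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_label, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-reaction mapping
#'
#' Expects a headerless two-column TSV: gene (KO) identifier, reaction
#' identifier. A gene may map to several reactions (one row each).
#'
#' @param path Path to the TSV file.
#' @return Named list mapping each gene ID to a character vector of reaction
#'   IDs.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "reaction"))
  as_gene_map(df)
}

#' Coerce a gene-to-reaction mapping to list form
#'
#' @param x Either a named list (gene -> character vector of reaction IDs) or
#'   a two-column data frame (gene, reaction).
#' @return Named list form of the mapping.
#' @export
as_gene_map <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("gene map data frame needs two columns (gene, reaction)")
    x <- split(as.character(x[[2L]]), as.character(x[[1L]]))
  }
  if (!is.list(x) || is.null(names(x))) stop("gene map must be a named list or two-column data frame")
  x <- lapply(x, function(v) unique(as.character(v)))
  if (any(lengths(x) == 0L)) stop("every gene must map to at least one reaction")
  x
}

#' Read an optional reaction coefficient table
#'
#' Three-column TSV with header: reaction_id, compound_id, coefficient.
#' Supplies stoichiometric coefficients missing from the reaction-direction
#' dialect; compounds absent from the table default to coefficient 1.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `reaction_id`, `compound_id`,
#'   `coefficient`.
#' @export
read_coefficients <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reaction_id", "compound_id", "coefficient")
  if (!all(need %in% colnames(df))) {
    stop("coefficient table must have columns: ", paste(need, collapse = ", "))
  }
  df$coefficient <- as.numeric(df$coefficient)
  if (any(!is.finite(df$coefficient)) || any(df$coefficient <= 0)) {
    stop("coefficients must be positive numbers")
  }
  df[need]
}

#' Align two feature tables on shared samples
#'
#' Restricts both matrices to the samples (columns) they share, in a common
#' order. Samples present in only one table are dropped with a message.
#'
#' @param a,b Matrices with sample IDs as column names.
#' @return List with elements `a` and `b`, column-aligned.
#' @export
align_samples <- function(a, b) {
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0L) stop("no shared samples between tables")
  dropped <- (ncol(a) - length(shared)) + (ncol(b) - length(shared))
  if (dropped > 0L) message("align_samples: dropped ", dropped, " unmatched sample column(s)")
  list(a = a[, shared, drop = FALSE], b = b[, shared, drop = FALSE])
}
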