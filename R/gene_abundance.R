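#' Infer community gene abundance from taxon abundances and genome content
#'
#' Predicts the metagenome of each sample as the product of per-taxon gene
#' (KO) copy numbers and taxon abundances:
#' `G[g, s] = sum_t abundance[t, s] * copies[t, g]`. This is the
#' taxonomy-based metagenome inference used when shotgun gene abundances
#' are unavailable; a PICRUSt-style prediction table can be used as the
#' genome content input.
#'
#' @param taxa Taxa-by-sample non-negative abundance matrix.
#' @param genomes Taxa-by-gene non-negative copy-number matrix.
#' @param normalizer Optional function applied to each sample column of G
#'   after inference (e.g., an external MUSiCC-style correction). Default
#'   is no transformation.
#' @param drop_zero_genes Drop genes with all-zero abundance (default TRUE).
#' @return Genes-by-samples matrix G.
#' @export
infer_gene_abundance <- function(taxa, genomes, normalizer = NULL,
                                 drop_zero_genes = TRUE) {
  if (any(taxa < 0, na.rm = TRUE) || any(genomes < 0, na.rm = TRUE)) {
    stop("abundances and copy numbers must be non-negative")
  }
  shared <- intersect(rownames(taxa), rownames(genomes))
  if (length(shared) == 0L) stop("no taxa shared between abundance table and genome content table")
  dropped <- setdiff(rownames(taxa), shared)
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped), " taxon/taxa without genome content: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  G <- t(genomes[shared, , drop = FALSE]) %*% taxa[shared, , drop = FALSE]
  if (!is.null(normalizer)) {
    stopifnot(is.function(normalizer))
    G <- apply(G, 2L, normalizer)
  }
  if (drop_zero_genes) {
    G <- G[rowSums(G != 0) > 0L, , drop = FALSE]
  }
  G
}

#' Sum metabolite rows that share a compound identifier
#'
#' Metabolomic peak tables may map several peaks to one KEGG compound ID;
#' such rows are summed entrywise. A missing value summed with a number is
#' treated as 0; a position missing in every duplicate row stays missing.
#'
#' @param mat Metabolites-by-samples matrix, possibly with duplicated row
#'   names.
#' @return Matrix with one row per compound ID, in first-occurrence order.
#' @export
collapse_duplicate_metabolites <- function(mat) {
  ids <- rownames(mat)
  if (is.null(ids)) stop("metabolite table must have row names")
  if (!anyDuplicated(ids)) return(mat)
  ord <- unique(ids)
  out <- matrix(NA_real_, length(ord), ncol(mat),
                dimnames = list(ord, colnames(mat)))
  for (id in ord) {
    rows <- mat[ids == id, , drop = FALSE]
    s <- colSums(rows, na.rm = TRUE)
    s[colSums(!is.na(rows)) == 0L] <- NA_real_
    out[id, ] <- s
  }
  out
}

#' Discard metabolites measured in too few samples
#'
#' Removes metabolite rows with nonzero, non-missing abundance in fewer
#' than `min_nonzero` samples; with the default of 5 this drops
#' metabolites nonzero in at most 4 samples and keeps those nonzero in 5.
#'
#' @param mat Metabolites-by-samples matrix.
#' @param min_nonzero Minimum number of samples with nonzero abundance
#'   required to retain a metabolite (default 5).
#' @return Filtered matrix.
#' @export
filter_rare_metabolites <- function(mat, min_nonzero = 5L) {
  min_nonzero <- as.integer(min_nonzero)
  stopifnot(min_nonzero >= 1L)
  n_nonzero <- rowSums(!is.na(mat) & mat != 0)
  drop <- n_nonzero < min_nonzero
  if (any(drop)) {
    message("filter_rare_metabolites: removing ", sum(drop), " metabolite(s): ",
            paste(utils::head(rownames(mat)[drop], 10L), collapse = ", "),
            if (sum(drop) > 10L) ", ..." else "")
  }
  out <- mat[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("all metabolites removed by the rare-metabolite filter")
  out
}
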