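#' Compute community-based metabolite potential (CMP) scores
#'
#' Multiplies the normalized stoichiometric impact matrix M by the gene
#' abundance matrix G: `CMP[m, s] = sum_g M[m, g] * G[g, s]`, restricted to
#' genes shared between the model and G. Positive scores indicate a
#' community capacity to accumulate the metabolite, negative scores a
#' capacity to deplete it. Scores are relative: only between-sample
#' differences are interpretable, and CMP is not a concentration or flux
#' prediction.
#'
#' @param model A `stoich_model` from [build_model].
#' @param G Genes-by-samples abundance matrix.
#' @return Metabolites-by-samples CMP score matrix.
#' @export
compute_cmp <- function(model, G) {
  shared <- intersect(model$genes, rownames(G))
  if (length(shared) == 0L) stop("no genes shared between model and gene abundance table")
  d_model <- length(model$genes) - length(shared)
  d_g <- nrow(G) - length(shared)
  if (d_model > 0L || d_g > 0L) {
    message("compute_cmp: ", d_g, " gene(s) in G absent from model, ",
            d_model, " model gene(s) absent from G; using ", length(shared),
            " shared gene(s)")
  }
  model$matrix[, shared, drop = FALSE] %*% G[shared, , drop = FALSE]
}

#' CMP scores attributable to a single taxon
#'
#' Recomputes metagenome content and CMP scores from the abundance of one
#' taxon alone (all other taxa ignored, no normalizer), the basis of key
#' species contributor analysis. With no normalizer, single-taxon CMP
#' tables sum to the community CMP table.
#'
#' @param model A `stoich_model`.
#' @param taxa Taxa-by-sample abundance matrix.
#' @param genomes Taxa-by-gene copy-number matrix.
#' @param taxon_id Identifier of the taxon, present in both tables.
#' @return Metabolites-by-samples CMP matrix; all-zero when the taxon has
#'   zero abundance everywhere or carries no model gene.
#' @export
compute_single_taxon_cmp <- function(model, taxa, genomes, taxon_id) {
  if (!taxon_id %in% rownames(taxa)) stop("unknown taxon in abundance table: ", taxon_id)
  if (!taxon_id %in% rownames(genomes)) stop("unknown taxon in genome table: ", taxon_id)
  G1 <- infer_gene_abundance(taxa[taxon_id, , drop = FALSE],
                             genomes[taxon_id, , drop = FALSE],
                             drop_zero_genes = FALSE)
  if (length(intersect(model$genes, rownames(G1))) == 0L) {
    return(matrix(0, length(model$metabolites), ncol(taxa),
                  dimnames = list(model$metabolites, colnames(taxa))))
  }
  suppressMessages(compute_cmp(model, G1))
}
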