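#' Configuration for contributor analysis
#'
#' @param species_corr_threshold A taxon is a key contributor for a
#'   metabolite when the Pearson correlation between its single-taxon CMP
#'   row and the community CMP row exceeds this value (default 0.5).
#' @param gene_corr_threshold A gene is a key contributor when zeroing its
#'   matrix link drops the Pearson correlation between original and
#'   perturbed CMP rows below this value (default 0.5).
#' @return A `contributor_config` list.
#' @export
contributor_config <- function(species_corr_threshold = 0.5,
                               gene_corr_threshold = 0.5) {
  stopifnot(species_corr_threshold > 0, species_corr_threshold < 1,
            gene_corr_threshold > 0, gene_corr_threshold < 1)
  structure(list(species_corr_threshold = species_corr_threshold,
                 gene_corr_threshold = gene_corr_threshold),
            class = "contributor_config")
}

#' Key species contributors to CMP scores
#'
#' For each (metabolite, taxon) pair, correlates (Pearson, across samples)
#' the CMP row computed from that taxon alone with the community CMP row.
#' Taxa whose correlation exceeds the threshold are key contributors. A
#' constant single-taxon row (the taxon carries no gene touching the
#' metabolite, or is absent) has undefined correlation and is never key:
#' there is no evidence of contribution.
#'
#' @param model A `stoich_model`.
#' @param taxa Taxa-by-sample abundance matrix.
#' @param genomes Taxa-by-gene copy-number matrix.
#' @param community_cmp Optional community CMP matrix; recomputed
#'   internally (no normalizer) when omitted, which is the contract the
#'   additivity of single-taxon scores relies on.
#' @param cfg A [contributor_config].
#' @return Data frame: `metabolite`, `taxon`, `correlation`, `is_key`.
#' @export
key_species <- function(model, taxa, genomes, community_cmp = NULL,
                        cfg = contributor_config()) {
  shared_taxa <- intersect(rownames(taxa), rownames(genomes))
  if (length(shared_taxa) == 0L) stop("no taxa shared between abundance and genome tables")
  if (is.null(community_cmp)) {
    G <- suppressWarnings(infer_gene_abundance(taxa, genomes))
    community_cmp <- suppressMessages(compute_cmp(model, G))
  }
  out <- vector("list", length(shared_taxa))
  for (k in seq_along(shared_taxa)) {
    t_id <- shared_taxa[k]
    st <- compute_single_taxon_cmp(model, taxa, genomes, t_id)
    st <- st[rownames(community_cmp), colnames(community_cmp), drop = FALSE]
    corr <- row_correlations(st, community_cmp)
    out[[k]] <- data.frame(metabolite = rownames(community_cmp),
                           taxon = t_id,
                           correlation = corr,
                           is_key = !is.na(corr) & corr > cfg$species_corr_threshold,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Pearson correlation between corresponding rows of two matrices; NA for
# constant rows.
row_correlations <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    suppressWarnings(stats::cor(a[i, ], b[i, ]))
  }, numeric(1L))
}

#' Key gene contributors to CMP scores
#'
#' For each metabolite and each gene with a nonzero link to it, recomputes
#' the metabolite's CMP row after zeroing that single matrix entry (the
#' row is deliberately not renormalized: the perturbation deletes one
#' link, it does not rebuild the model). Genes whose deletion drops the
#' Pearson correlation between original and perturbed rows below the
#' threshold are key. When the perturbed row is constant (the gene was the
#' metabolite's only link) the correlation is undefined and the gene is
#' key: deleting the only link destroys the score.
#'
#' @param model A `stoich_model`.
#' @param G Genes-by-samples abundance matrix.
#' @param cfg A [contributor_config].
#' @return Data frame: `metabolite`, `gene`, `correlation`, `is_key`.
#' @export
key_genes <- function(model, G, cfg = contributor_config()) {
  shared <- intersect(model$genes, rownames(G))
  if (length(shared) == 0L) stop("no genes shared between model and gene abundance table")
  M <- model$matrix[, shared, drop = FALSE]
  Gs <- G[shared, , drop = FALSE]
  base <- M %*% Gs
  out <- vector("list", 0L)
  for (m in rownames(M)) {
    gs <- shared[M[m, ] != 0]
    if (length(gs) == 0L) next
    corr <- vapply(gs, function(g) {
      pert <- base[m, ] - M[m, g] * Gs[g, ]
      suppressWarnings(stats::cor(base[m, ], pert))
    }, numeric(1L))
    out[[length(out) + 1L]] <- data.frame(
      metabolite = m, gene = gs, correlation = corr,
      is_key = is.na(corr) | corr < cfg$gene_corr_threshold,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Key reaction contributors derived from key genes
#'
#' Every reaction through which a key gene touches its metabolite (per the
#' model's provenance records) is a key reaction contributor, annotated
#' with its role: it either produces or consumes the metabolite.
#'
#' @param model A `stoich_model`.
#' @param key_gene_table Output of [key_genes] (rows with `is_key = FALSE`
#'   are ignored).
#' @return Data frame: `metabolite`, `reaction_id`, `role`, `gene`.
#' @export
key_reactions <- function(model, key_gene_table) {
  kg <- key_gene_table[key_gene_table$is_key, , drop = FALSE]
  prov <- model$provenance
  hits <- merge(kg[, c("metabolite", "gene")], prov,
                by = c("metabolite", "gene"))
  out <- unique(hits[, c("metabolite", "reaction_id", "role", "gene")])
  rownames(out) <- NULL
  out
}

#' Classify synthesis versus degradation drive
#'
#' A metabolite whose key reaction contributors all produce it is driven
#' primarily by synthesis; one whose key reactions all consume it is
#' driven by degradation; both roles present is mixed; no key reactions is
#' none.
#'
#' @param key_reaction_table Output of [key_reactions].
#' @param metabolites Metabolite universe for the result (defaults to the
#'   metabolites present in the table).
#' @return Named character vector of drive labels (`synthesis`,
#'   `degradation`, `mixed`, `none`).
#' @export
classify_drive <- function(key_reaction_table,
                           metabolites = unique(key_reaction_table$metabolite)) {
  drive <- setNames(rep("none", length(metabolites)), metabolites)
  for (m in intersect(metabolites, key_reaction_table$metabolite)) {
    roles <- unique(key_reaction_table$role[key_reaction_table$metabolite == m])
    drive[m] <- if (setequal(roles, "produces")) "synthesis"
      else if (setequal(roles, "consumes")) "degradation"
      else "mixed"
  }
  drive
}

#' Full contributor report
#'
#' Runs key species, key gene, and key reaction analyses and classifies
#' each metabolite's synthesis/degradation drive.
#'
#' @param model A `stoich_model`.
#' @param taxa,genomes Taxon abundance and genome content tables (species
#'   analysis is skipped when either is NULL).
#' @param G Gene abundance matrix; inferred from `taxa`/`genomes` when
#'   omitted.
#' @param cfg A [contributor_config].
#' @return List with data frames `species`, `genes`, `reactions`, and the
#'   named `drive` vector over model metabolites.
#' @export
contributor_report <- function(model, taxa = NULL, genomes = NULL, G = NULL,
                               cfg = contributor_config()) {
  if (is.null(G)) {
    if (is.null(taxa) || is.null(genomes)) stop("need either G or taxa + genomes")
    G <- suppressWarnings(infer_gene_abundance(taxa, genomes))
  }
  species <- if (!is.null(taxa) && !is.null(genomes)) {
    key_species(model, taxa, genomes, cfg = cfg)
  } else NULL
  genes <- key_genes(model, G, cfg = cfg)
  reactions <- key_reactions(model, genes)
  drive <- classify_drive(reactions, metabolites = model$metabolites)
  list(species = species, genes = genes, reactions = reactions, drive = drive)
}
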