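#' Run the full integration pipeline
#'
#' Orchestrates model construction, gene abundance inference (or ingestion
#' of a precomputed gene table), metabolite preprocessing, CMP scoring,
#' prediction, contributor analysis, and (optionally) the null models,
#' writing TSV outputs and a JSON summary to an output directory.
#'
#' The configuration is a nested list (or the path to a YAML file with the
#' same structure):
#' \preformatted{
#' inputs:
#'   reaction_file:        reaction_mapformula.lst-dialect text (required)
#'   gene_map_file:        2-column TSV gene -> reaction (required)
#'   coefficient_file:     optional reaction/compound/coefficient TSV
#'   taxa_file:            taxa x samples TSV   \  either these two
#'   genome_file:          taxa x genes TSV     /  ...
#'   gene_abundance_file:  genes x samples TSV  -  or this one
#'   metabolite_file:      compounds x samples TSV (required)
#'   category_file:        optional 2-column TSV compound -> category
#' output_dir: directory for results (required)
#' seed: integer RNG seed
#' min_nonzero_samples: rare-metabolite cutoff (default 5)
#' network:      arguments for network_filter_config()
#' prediction:   arguments for prediction_config()
#' contributors: run: true/false plus contributor_config() arguments
#' null_models:  run: false plus null_model_config() arguments
#' adjacency_test: run: false
#' }
#'
#' @param config Nested configuration list or path to a YAML file.
#' @return The run summary (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  inp <- cfg$inputs
  if (is.null(inp$reaction_file) || is.null(inp$gene_map_file) ||
      is.null(inp$metabolite_file) || is.null(cfg$output_dir)) {
    stop("config requires inputs$reaction_file, inputs$gene_map_file, inputs$metabolite_file, output_dir")
  }
  for (f in unlist(inp)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  net_cfg <- do.call(network_filter_config, cfg$network %||% list())
  pred_cfg <- do.call(prediction_config, cfg$prediction %||% list())
  contrib_opts <- cfg$contributors %||% list()
  contrib_run <- contrib_opts$run %||% TRUE
  contrib_opts$run <- NULL
  contrib_cfg <- do.call(contributor_config, contrib_opts)

  model <- stage("build-network", {
    coefs <- if (!is.null(inp$coefficient_file)) read_coefficients(inp$coefficient_file)
    entries <- parse_reaction_map(inp$reaction_file, coefficients = coefs)
    build_model(entries, read_gene_map(inp$gene_map_file), cfg = net_cfg)
  })
  write_model(model, file.path(out_dir, "model.tsv"),
              file.path(out_dir, "model_provenance.tsv"))

  taxa <- NULL; genomes <- NULL
  if (is.null(inp$gene_abundance_file) &&
      (is.null(inp$taxa_file) || is.null(inp$genome_file))) {
    stop("need either gene_abundance_file or taxa_file + genome_file")
  }
  if (!is.null(inp$taxa_file) && !is.null(inp$genome_file)) {
    taxa <- stage("infer-genes", read_feature_table(inp$taxa_file))
    genomes <- stage("infer-genes", read_feature_table(inp$genome_file))
  }
  G <- stage("infer-genes", {
    if (!is.null(inp$gene_abundance_file)) {
      read_feature_table(inp$gene_abundance_file)
    } else {
      infer_gene_abundance(taxa, genomes)
    }
  })
  write_feature_table(G, file.path(out_dir, "gene_abundance.tsv"), "gene_id")

  met <- stage("metabolite-preprocessing", {
    m <- read_feature_table(inp$metabolite_file)
    m <- collapse_duplicate_metabolites(m)
    filter_rare_metabolites(m, cfg$min_nonzero_samples %||% 5L)
  })

  cmp <- stage("cmp", compute_cmp(model, G))
  write_feature_table(cmp, file.path(out_dir, "cmp_scores.tsv"), "compound_id")

  results <- stage("predict", predict_metabolites(cmp, met, pred_cfg))
  utils::write.table(results, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  contrib <- NULL
  if (isTRUE(contrib_run)) {
    contrib <- stage("contributors",
                     contributor_report(model, taxa = taxa, genomes = genomes,
                                        G = G, cfg = contrib_cfg))
    write_contributors(contrib, file.path(out_dir, "contributors.tsv"))
  }

  classes <- setNames(results$class, results$metabolite)
  null_res <- NULL
  nm_opts <- cfg$null_models %||% list()
  if (isTRUE(nm_opts$run)) {
    nm_opts$run <- NULL
    null_cfg <- do.call(null_model_config, nm_opts)
    null_res <- stage("null-network",
                      network_null_test(model, G, met, pred_cfg, null_cfg))
  }
  adj_res <- NULL
  adj_opts <- cfg$adjacency_test %||% list()
  if (isTRUE(adj_opts$run)) {
    adj_opts$run <- NULL
    adj_cfg <- do.call(null_model_config, adj_opts)
    adj_res <- stage("adjacency-test",
                     adjacency_permutation_test(metabolite_adjacency(model),
                                                classes, adj_cfg))
  }

  categories <- if (!is.null(inp$category_file)) {
    df <- utils::read.delim(inp$category_file, header = FALSE,
                            stringsAsFactors = FALSE)
    setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  }
  cat_summary <- summarize_by_category(results, categories)
  utils::write.table(cat_summary, file.path(out_dir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  n_eval <- sum(results$class != "not_evaluable")
  summary <- list(
    package_version = as.character(utils::packageVersion("cmpscore")),
    seed = cfg$seed,
    n_model_metabolites = length(model$metabolites),
    n_model_genes = length(model$genes),
    n_currency_removed = length(model$currency_removed),
    n_measured_metabolites = nrow(met),
    n_metabolites_tested = nrow(results),
    n_evaluable = n_eval,
    n_well_predicted = sum(results$class == "well_predicted"),
    n_anti_predicted = sum(results$class == "anti_predicted"),
    frac_well_predicted = if (n_eval) sum(results$class == "well_predicted") / n_eval else NA,
    frac_anti_predicted = if (n_eval) sum(results$class == "anti_predicted") / n_eval else NA,
    network_null = if (!is.null(null_res)) {
      null_res[c("observed", "p_value", "n_replicates", "n_failed")]
    },
    adjacency_test = if (!is.null(adj_res)) {
      list(observed = as.list(adj_res$observed),
           p_values = as.list(adj_res$p_values))
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(model = model, gene_abundance = G, cmp = cmp,
                 results = results, contributors = contrib,
                 network_null = null_res, adjacency_test = adj_res,
                 summary = summary))
}

write_contributors <- function(contrib, path) {
  rows <- list()
  if (!is.null(contrib$species)) {
    s <- contrib$species
    rows[[1L]] <- data.frame(metabolite = s$metabolite,
                             contributor_type = "species",
                             contributor_id = s$taxon,
                             correlation = s$correlation,
                             is_key = s$is_key, role = NA_character_,
                             stringsAsFactors = FALSE)
  }
  g <- contrib$genes
  rows[[length(rows) + 1L]] <- data.frame(metabolite = g$metabolite,
                                          contributor_type = "gene",
                                          contributor_id = g$gene,
                                          correlation = g$correlation,
                                          is_key = g$is_key,
                                          role = NA_character_,
                                          stringsAsFactors = FALSE)
  r <- contrib$reactions
  if (nrow(r)) {
    rows[[length(rows) + 1L]] <- data.frame(metabolite = r$metabolite,
                                            contributor_type = "reaction",
                                            contributor_id = r$reaction_id,
                                            correlation = NA_real_,
                                            is_key = TRUE, role = r$role,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$drive <- unname(contrib$drive[out$metabolite])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize prediction classes by metabolite category
#'
#' @param results Prediction table from [predict_metabolites].
#' @param category_map Optional named character vector mapping metabolite
#'   IDs to category labels; unmapped metabolites are grouped as
#'   `unassigned`.
#' @return Data frame of per-category class counts.
#' @export
summarize_by_category <- function(results, category_map = NULL) {
  cats <- if (is.null(category_map)) rep(NA_character_, nrow(results))
    else unname(category_map[results$metabolite])
  cats[is.na(cats)] <- "unassigned"
  tab <- table(category = cats, class = results$class)
  df <- as.data.frame.matrix(tab)
  data.frame(category = rownames(df), df, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
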