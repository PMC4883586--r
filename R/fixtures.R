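#' Specification for a synthetic community fixture
#'
#' Describes a self-contained synthetic data set: a sparse log-normal
#' taxon abundance table, binary genome gene content, a KEGG-dialect
#' reaction network linking genes to metabolites (with reversible and
#' currency-metabolite decoys), and a measured metabolite table generated
#' as a linear-plus-noise function of the true CMP signal. Metabolites are
#' planted in three classes: producer-controlled (abundance follows the
#' community's capacity to act on it, positive coupling), consumer- or
#' environment-controlled (negative coupling), and independent (pure
#' noise).
#'
#' Each planted metabolite is produced by one or two dedicated
#' forward reactions whose genes are carried by a single generating taxon,
#' so single-taxon CMP analysis has unambiguous ground truth. Currency
#' decoys are compounds touched by reactions spanning
#' `currency_gene_count` distinct genes, which the model-construction
#' currency filter should remove at its default cutoff of 30; reversible
#' decoys are compound pairs linked only by reversible reactions, which
#' the directionality filter discards.
#'
#' @param n_taxa,n_genes,n_metabolites,n_samples Fixture dimensions. The
#'   gene pool must cover the planted reactions plus decoys, otherwise
#'   generation errors as infeasible.
#' @param frac_producer,frac_consumer,frac_independent Class proportions;
#'   must sum to 1.
#' @param coupling_strength Signal multiplier applied to the standardized
#'   true CMP row (default 3, i.e. a 3:1 signal-to-noise ratio against
#'   unit-variance noise).
#' @param noise_sd Standard deviation of the additive measurement noise
#'   (> 0).
#' @param genome_density Bernoulli probability that a taxon carries a
#'   non-planted (decoy) gene.
#' @param frac_two_reactions Fraction of metabolites produced by two
#'   reactions/genes rather than one.
#' @param n_currency,currency_gene_count Number of currency decoy
#'   compounds and the number of single-gene reactions touching each.
#' @param n_reversible Number of reversible decoy reactions.
#' @param taxon_zero_prob Per-entry probability that a taxon abundance is
#'   zeroed (sparsity).
#' @param rng_seed Integer seed; the whole fixture is reproducible from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_taxa = 15L, n_genes = 200L, n_metabolites = 60L,
                         n_samples = 20L,
                         frac_producer = 0.3, frac_consumer = 0.2,
                         frac_independent = 0.5,
                         coupling_strength = 3, noise_sd = 1,
                         genome_density = 0.35,
                         frac_two_reactions = 0.3,
                         n_currency = 2L, currency_gene_count = 32L,
                         n_reversible = 10L,
                         taxon_zero_prob = 0.3,
                         rng_seed = 1L) {
  stopifnot(n_samples >= 6L, n_taxa >= 1L, n_metabolites >= 1L,
            abs(frac_producer + frac_consumer + frac_independent - 1) <= 1e-9,
            coupling_strength >= 0, noise_sd > 0,
            genome_density > 0, genome_density <= 1,
            taxon_zero_prob >= 0, taxon_zero_prob < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic community fixture with planted ground truth
#'
#' Draws a community according to a [fixture_spec] and runs the model
#' construction and CMP scoring pipeline on it to plant metabolite
#' signals: producer-controlled metabolites get measured abundance
#' `coupling_strength * standardize(CMP_true) + Normal(0, noise_sd)`,
#' consumer-controlled metabolites the same with negated coupling, and
#' independent metabolites pure noise. With `coupling_strength = 0` every
#' metabolite is recorded as null-class.
#'
#' @param spec A [fixture_spec].
#' @return List with `taxa` (taxa x samples), `genomes` (taxa x genes),
#'   `reaction_lines` (mapformula-dialect text), `gene_map` (two-column
#'   data frame), `metabolites` (measured metabolite x sample matrix),
#'   `truth` (data frame: metabolite, class, generating_taxon, genes),
#'   plus the intermediate `model`, `gene_abundance`, and `cmp` objects
#'   and the `spec` itself.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  nm <- spec$n_metabolites; nt <- spec$n_taxa; ns <- spec$n_samples

  mets <- sprintf("C%05d", seq_len(nm))
  precursors <- sprintf("C1%04d", seq_len(nm))
  taxa_ids <- sprintf("T%03d", seq_len(nt))
  samples <- sprintf("S%03d", seq_len(ns))

  n_rxn_per_met <- 1L + stats::rbinom(nm, 1L, spec$frac_two_reactions)
  n_signal_genes <- sum(n_rxn_per_met)
  n_currency_genes <- spec$n_currency * spec$currency_gene_count
  n_needed <- n_signal_genes + n_currency_genes + spec$n_reversible
  if (n_needed > spec$n_genes) {
    stop("fixture spec infeasible: needs ", n_needed, " genes but n_genes = ",
         spec$n_genes)
  }
  genes <- sprintf("K%05d", seq_len(spec$n_genes))

  lines <- character(0L)
  map_rows <- list()
  rxn_counter <- 0L
  gene_cursor <- 0L
  next_gene <- function() { gene_cursor <<- gene_cursor + 1L; genes[gene_cursor] }
  next_rxn <- function() { rxn_counter <<- rxn_counter + 1L; sprintf("R%05d", rxn_counter) }

  gen_taxon <- sample(taxa_ids, nm, replace = TRUE)
  signal_genes <- vector("list", nm)
  for (i in seq_len(nm)) {
    gs <- character(n_rxn_per_met[i])
    for (k in seq_len(n_rxn_per_met[i])) {
      g <- next_gene(); r <- next_rxn()
      gs[k] <- g
      lines <- c(lines, sprintf("%s: 00%03d: %s => %s", r,
                                sample(1:9, 1L) * 10L, precursors[i], mets[i]))
      map_rows[[length(map_rows) + 1L]] <- data.frame(gene = g, reaction = r)
    }
    signal_genes[[i]] <- gs
  }

  # currency decoys: each currency compound consumed by many single-gene
  # reactions, so it associates with >= currency_gene_count distinct genes
  currency_ids <- sprintf("C888%02d", seq_len(spec$n_currency))
  junk_counter <- 0L
  for (cc in currency_ids) {
    for (k in seq_len(spec$currency_gene_count)) {
      g <- next_gene(); r <- next_rxn()
      junk_counter <- junk_counter + 1L
      lines <- c(lines, sprintf("%s: 00900: %s => C7%04d", r, cc, junk_counter))
      map_rows[[length(map_rows) + 1L]] <- data.frame(gene = g, reaction = r)
    }
  }

  # reversible decoys: compound pairs linked only by reversible reactions
  for (k in seq_len(spec$n_reversible)) {
    g <- next_gene(); r <- next_rxn()
    lines <- c(lines, sprintf("%s: 00800: C6%04d <=> C6%04d", r,
                              2L * k - 1L, 2L * k))
    map_rows[[length(map_rows) + 1L]] <- data.frame(gene = g, reaction = r)
  }
  gene_map_df <- do.call(rbind, map_rows)

  # genomes: planted genes sit in their generating taxon only; decoy genes
  # are Bernoulli across taxa
  genomes <- matrix(stats::rbinom(nt * spec$n_genes, 1L, spec$genome_density),
                    nt, spec$n_genes, dimnames = list(taxa_ids, genes))
  for (i in seq_len(nm)) {
    genomes[, signal_genes[[i]]] <- 0L
    genomes[gen_taxon[i], signal_genes[[i]]] <- 1L
  }

  taxa <- matrix(stats::rlnorm(nt * ns, meanlog = 0, sdlog = 1) *
                   stats::rbinom(nt * ns, 1L, 1 - spec$taxon_zero_prob),
                 nt, ns, dimnames = list(taxa_ids, samples))

  entries <- parse_reaction_map(lines)
  model <- suppressWarnings(build_model(entries, gene_map_df))
  G <- suppressWarnings(infer_gene_abundance(taxa, genomes))
  cmp <- suppressMessages(compute_cmp(model, G))

  cls <- rep("null", nm)
  if (spec$coupling_strength > 0) {
    n_prod <- round(spec$frac_producer * nm)
    n_cons <- round(spec$frac_consumer * nm)
    planted <- sample.int(nm, n_prod + n_cons)
    cls[planted[seq_len(n_prod)]] <- "should_be_well_predicted"
    cls[planted[n_prod + seq_len(n_cons)]] <- "should_be_anti_predicted"
  }

  met_mat <- matrix(stats::rnorm(nm * ns, 0, spec$noise_sd), nm, ns,
                    dimnames = list(mets, samples))
  for (i in seq_len(nm)) {
    if (cls[i] == "null") next
    row <- cmp[mets[i], ]
    if (stats::sd(row) == 0) { cls[i] <- "null"; next }
    z <- as.numeric(scale(row))
    sign_i <- if (cls[i] == "should_be_well_predicted") 1 else -1
    met_mat[i, ] <- met_mat[i, ] + sign_i * spec$coupling_strength * z
  }

  truth <- data.frame(
    metabolite = mets,
    class = cls,
    generating_taxon = ifelse(cls == "null", NA_character_, gen_taxon),
    genes = vapply(signal_genes, paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  list(taxa = taxa, genomes = genomes, reaction_lines = lines,
       gene_map = gene_map_df, metabolites = met_mat, truth = truth,
       model = model, gene_abundance = G, cmp = cmp, spec = spec)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' @param fixture Output of [generate_fixture].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    taxa = file.path(dir, "taxa.tsv"),
    genomes = file.path(dir, "genomes.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    reactions = file.path(dir, "reaction_mapformula.lst"),
    gene_map = file.path(dir, "gene_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_feature_table(fixture$taxa, paths$taxa, id_label = "taxon_id")
  write_feature_table(fixture$genomes, paths$genomes, id_label = "taxon_id")
  write_feature_table(fixture$metabolites, paths$metabolites, id_label = "compound_id")
  writeLines(fixture$reaction_lines, paths$reactions)
  utils::write.table(fixture$gene_map, paths$gene_map, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fixture$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Recovery rates of planted metabolite classes
#'
#' Compares prediction results against the fixture's planted truth.
#' Sensitivity for producer-controlled metabolites is the fraction
#' classified well-predicted; sensitivity for consumer-controlled
#' metabolites the fraction classified anti-predicted; specificity is the
#' fraction of null metabolites classified neither.
#'
#' @param truth Truth table from [generate_fixture].
#' @param results Prediction table from [predict_metabolites].
#' @return List with `sensitivity_producer`, `sensitivity_consumer`,
#'   `specificity_null`, class counts `n_producer`/`n_consumer`/`n_null`,
#'   and the `confusion` cross-table.
#' @export
evaluate_recovery <- function(truth, results) {
  j <- merge(truth, results, by = "metabolite")
  prod <- j$class.x == "should_be_well_predicted"
  cons <- j$class.x == "should_be_anti_predicted"
  null <- j$class.x == "null"
  list(
    sensitivity_producer = if (any(prod)) mean(j$class.y[prod] == "well_predicted") else NA_real_,
    sensitivity_consumer = if (any(cons)) mean(j$class.y[cons] == "anti_predicted") else NA_real_,
    specificity_null = if (any(null)) {
      mean(!j$class.y[null] %in% c("well_predicted", "anti_predicted"))
    } else NA_real_,
    n_producer = sum(prod), n_consumer = sum(cons), n_null = sum(null),
    confusion = table(planted = j$class.x, predicted = j$class.y)
  )
}

#' Precision and recall of key-species recovery on a planted fixture
#'
#' Restricts the key-species table to planted (non-null) metabolites and
#' scores key calls against the generating taxon recorded in the truth
#' table.
#'
#' @param truth Truth table from [generate_fixture].
#' @param key_species_table Output of [key_species].
#' @return List with `precision`, `recall`, `n_key_calls`.
#' @export
evaluate_key_species <- function(truth, key_species_table) {
  planted <- truth[truth$class != "null", , drop = FALSE]
  ks <- key_species_table[key_species_table$is_key &
                            key_species_table$metabolite %in% planted$metabolite, ,
                          drop = FALSE]
  gen <- setNames(planted$generating_taxon, planted$metabolite)
  correct <- ks$taxon == gen[ks$metabolite]
  recalled <- vapply(planted$metabolite, function(m) {
    any(ks$metabolite == m & ks$taxon == gen[m])
  }, NA)
  list(precision = if (nrow(ks)) mean(correct) else NA_real_,
       recall = mean(recalled),
       n_key_calls = nrow(ks))
}
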