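#' Configuration for null-model testing
#'
#' @param n_random_networks Number of randomized networks for the
#'   network-level null (default 100).
#' @param n_edge_swaps Double-edge swaps per randomized network (default
#'   5000).
#' @param n_label_permutations Permutations for the metabolite-label
#'   adjacency test (default 1000).
#' @param rng_seed Optional integer seed.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_random_networks = 100L, n_edge_swaps = 5000L,
                              n_label_permutations = 1000L, rng_seed = NULL) {
  n_random_networks <- as.integer(n_random_networks)
  n_edge_swaps <- as.integer(n_edge_swaps)
  n_label_permutations <- as.integer(n_label_permutations)
  stopifnot(n_random_networks >= 1L, n_edge_swaps >= 1L,
            n_label_permutations >= 1L)
  structure(list(n_random_networks = n_random_networks,
                 n_edge_swaps = n_edge_swaps,
                 n_label_permutations = n_label_permutations,
                 rng_seed = rng_seed),
            class = "null_model_config")
}

#' Degree-preserving randomization of the gene-metabolite network
#'
#' Treats the pre-normalization impact matrix as a signed bipartite
#' gene-metabolite graph and applies double-edge swaps restricted to
#' same-sign edge pairs: edges (g1, m1) and (g2, m2) become (g2, m1) and
#' (g1, m2), with the edge weights travelling with the swap. Swaps that
#' would create a duplicate or sign-conflicting edge are rejected, so
#' every node retains its signed degree (each metabolite keeps its number
#' of producing and consuming links, each gene its producer/consumer role
#' balance). The shuffled raw matrix is rebuilt into a model with rows
#' renormalized.
#'
#' @param model A `stoich_model`.
#' @param cfg A [null_model_config]; `n_edge_swaps` successful swaps are
#'   attempted, bounded by 100x as many proposals (a warning reports the
#'   achieved count when fewer succeed).
#' @return A `stoich_model` with shuffled links (empty provenance), with
#'   attribute `n_swaps_achieved`.
#' @export
shuffle_network <- function(model, cfg = null_model_config()) {
  raw <- model$raw
  idx <- which(raw != 0, arr.ind = TRUE)
  w <- raw[idx]
  if (sum(w > 0) < 2L || sum(w < 0) < 2L) {
    stop("need at least 2 edges of each sign to shuffle the network")
  }
  em <- idx[, 1L]
  eg <- idx[, 2L]
  present <- raw != 0
  pos <- which(w > 0)
  neg <- which(w < 0)
  p_pos <- length(pos) / length(w)

  target <- cfg$n_edge_swaps
  max_attempts <- 100L * target
  done <- 0L; attempts <- 0L
  while (done < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    grp <- if (stats::runif(1L) < p_pos) pos else neg
    k <- grp[sample.int(length(grp), 2L)]
    a <- k[1L]; b <- k[2L]
    m1 <- em[a]; g1 <- eg[a]; m2 <- em[b]; g2 <- eg[b]
    if (m1 == m2 || g1 == g2) next
    if (present[m1, g2] || present[m2, g1]) next
    present[m1, g1] <- FALSE; present[m2, g2] <- FALSE
    present[m1, g2] <- TRUE; present[m2, g1] <- TRUE
    eg[a] <- g2; eg[b] <- g1
    done <- done + 1L
  }
  if (done < target) {
    warning("achieved ", done, " of ", target, " requested edge swaps")
  }
  raw2 <- matrix(0, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  raw2[cbind(em, eg)] <- w

  out <- structure(list(
    matrix = normalize_rows(raw2),
    raw = raw2,
    metabolites = rownames(raw2),
    genes = colnames(raw2),
    provenance = model$provenance[0, , drop = FALSE],
    currency_removed = model$currency_removed,
    gene_map = model$gene_map,
    directions = model$directions
  ), class = "stoich_model")
  attr(out, "n_swaps_achieved") <- done
  out
}

#' Network-randomization test for the number of well-predicted metabolites
#'
#' Reruns the prediction stage end-to-end on randomized models and asks
#' whether the real network yields more well-predicted metabolites than
#' its degree-preserving randomizations:
#' `p = (#\{random count >= observed\} + 1) / (n + 1)`. Replicates whose
#' pipeline fails are excluded with a message.
#'
#' @param model A `stoich_model`.
#' @param G Genes-by-samples abundance matrix.
#' @param met Metabolites-by-samples measured abundance matrix.
#' @param pred_cfg A [prediction_config] (its `rng_seed` is ignored here so
#'   the null stream stays reproducible from `null_cfg$rng_seed`).
#' @param null_cfg A [null_model_config].
#' @return List with `observed`, `random_counts`, `p_value`,
#'   `n_replicates`, `n_failed`.
#' @export
network_null_test <- function(model, G, met,
                              pred_cfg = prediction_config(),
                              null_cfg = null_model_config()) {
  if (!is.null(null_cfg$rng_seed)) set.seed(null_cfg$rng_seed)
  pred_cfg$rng_seed <- NULL
  run_once <- function(m) {
    res <- suppressMessages(predict_metabolites(compute_cmp(m, G), met, pred_cfg))
    sum(res$class == "well_predicted")
  }
  observed <- run_once(model)
  counts <- rep(NA_integer_, null_cfg$n_random_networks)
  for (i in seq_len(null_cfg$n_random_networks)) {
    counts[i] <- tryCatch(run_once(shuffle_network(model, null_cfg)),
                          error = function(e) NA_integer_)
  }
  ok <- !is.na(counts)
  if (any(!ok)) message("network_null_test: ", sum(!ok), " replicate(s) failed and were excluded")
  list(observed = observed,
       random_counts = counts[ok],
       p_value = (sum(counts[ok] >= observed) + 1) / (sum(ok) + 1),
       n_replicates = sum(ok),
       n_failed = sum(!ok))
}

#' Metabolite-label permutation test for anti/well adjacency
#'
#' Tests whether anti-predicted metabolites sit next to well-predicted
#' metabolites in the reaction network more often than chance. The
#' network topology is held fixed while metabolite class labels are
#' shuffled over node positions; adjacency counts (distinct metabolite
#' pairs in which the anti-predicted member is synthesized from, depleted
#' into, or reversibly connected to the well-predicted member) are
#' recomputed per permutation, giving upper-tail empirical p-values per
#' link type and overall.
#'
#' @param adjacency Output of [metabolite_adjacency].
#' @param classes Named character vector of prediction classes per
#'   metabolite (from [predict_metabolites]); network nodes without a
#'   class are carried as `unclassified` and permuted with the rest.
#' @param cfg A [null_model_config].
#' @return List with `observed` (counts per link type and `total`),
#'   `p_values`, `permuted` (permutation-by-type count matrix), and
#'   `n_permutations`. With no anti-predicted or no well-predicted
#'   metabolite in the network the result is degenerate: all counts 0,
#'   p = 1.
#' @export
adjacency_permutation_test <- function(adjacency, classes,
                                       cfg = null_model_config()) {
  types <- c("synthesizing", "depleting", "reversible")
  nodes <- unique(c(adjacency$met_u, adjacency$met_v))
  cl <- classes[nodes]
  cl[is.na(cl)] <- "unclassified"
  names(cl) <- nodes

  u_idx <- match(adjacency$met_u, nodes)
  v_idx <- match(adjacency$met_v, nodes)
  pair_key <- paste(pmin(adjacency$met_u, adjacency$met_v),
                    pmax(adjacency$met_u, adjacency$met_v))
  count_links <- function(lab) {
    hit <- lab[u_idx] == "well_predicted" & lab[v_idx] == "anti_predicted"
    vapply(types, function(tp) {
      length(unique(pair_key[hit & adjacency$link_type == tp]))
    }, integer(1L))
  }

  zero <- setNames(c(0L, 0L, 0L, 0L), c(types, "total"))
  if (!any(cl == "anti_predicted") || !any(cl == "well_predicted") ||
      nrow(adjacency) == 0L) {
    return(list(observed = zero,
                p_values = setNames(rep(1, 4L), c(types, "total")),
                permuted = NULL,
                n_permutations = 0L))
  }

  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  obs <- count_links(cl)
  obs_total <- c(obs, total = sum(obs))
  np <- cfg$n_label_permutations
  perm <- matrix(0L, np, 4L, dimnames = list(NULL, c(types, "total")))
  for (k in seq_len(np)) {
    ck <- count_links(unname(cl)[sample.int(length(cl))])
    perm[k, ] <- c(ck, sum(ck))
  }
  p <- vapply(c(types, "total"), function(nm) {
    (sum(perm[, nm] >= obs_total[nm]) + 1) / (np + 1)
  }, numeric(1L))
  list(observed = obs_total, p_values = p, permuted = perm,
       n_permutations = np)
}
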