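signed_degrees <- function(raw) {
  list(row_pos = rowSums(raw > 0), row_neg = rowSums(raw < 0),
       col_pos = colSums(raw > 0), col_neg = colSums(raw < 0))
}

test_that("edge shuffling preserves signed degrees, edge count, and weights", {
  set.seed(51)
  fx <- generate_fixture(fixture_spec(n_metabolites = 15, n_genes = 120,
                                      n_samples = 8, rng_seed = 51))
  before <- signed_degrees(fx$model$raw)
  sh <- shuffle_network(fx$model, null_model_config(n_edge_swaps = 5000))
  after <- signed_degrees(sh$raw)
  expect_equal(after, before)
  expect_equal(sum(sh$raw != 0), sum(fx$model$raw != 0))
  expect_equal(sum(abs(sh$raw)), sum(abs(fx$model$raw)))
  expect_equal(sort(sh$raw[sh$raw != 0]), sort(fx$model$raw[fx$model$raw != 0]))
  # rebuilt rows are renormalized
  M <- sh$matrix
  for (r in seq_len(nrow(M))) {
    if (any(M[r, ] < 0)) expect_equal(sum(M[r, ][M[r, ] < 0]), -1, tolerance = 1e-9)
    if (any(M[r, ] > 0)) expect_equal(sum(M[r, ][M[r, ] > 0]), 1, tolerance = 1e-9)
  }
})

test_that("two disjoint same-sign edges admit exactly one alternative pairing", {
  raw <- matrix(0, 4, 4, dimnames = list(paste0("m", 1:4), paste0("g", 1:4)))
  raw["m1", "g1"] <- 2; raw["m2", "g2"] <- 3     # positive pair
  raw["m3", "g3"] <- -1; raw["m4", "g4"] <- -4   # negative pair
  model <- structure(list(matrix = raw, raw = raw,
                          metabolites = rownames(raw), genes = colnames(raw),
                          provenance = data.frame(), currency_removed = character(),
                          gene_map = list(), directions = list()),
                     class = "stoich_model")
  set.seed(52)
  sh <- shuffle_network(model, null_model_config(n_edge_swaps = 1))
  expect_equal(attr(sh, "n_swaps_achieved"), 1L)
  pos_cells <- which(sh$raw > 0, arr.ind = TRUE)
  neg_cells <- which(sh$raw < 0, arr.ind = TRUE)
  # each sign group is either the original pairing or its unique swap
  expect_true(all(pos_cells[, 1] %in% 1:2) && all(pos_cells[, 2] %in% 1:2))
  expect_true(all(neg_cells[, 1] %in% 3:4) && all(neg_cells[, 2] %in% 3:4))
  expect_equal(signed_degrees(sh$raw), signed_degrees(raw))
  expect_false(identical(sh$raw, raw))  # the single swap changed one group
})

test_that("adjacency test degenerates to p = 1 without both classes", {
  adj <- data.frame(met_u = "A", met_v = "B", link_type = "synthesizing",
                    reaction_id = "R1")
  res <- adjacency_permutation_test(adj, c(A = "well_predicted",
                                           B = "not_significant"))
  expect_true(all(res$observed == 0))
  expect_true(all(res$p_values == 1))
})

test_that("a class-complete adjacency graph is permutation invariant", {
  nodes <- c("a1", "a2", "w1", "w2")
  pairs <- expand.grid(met_u = nodes, met_v = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$met_u != pairs$met_v, ]
  adj <- data.frame(pairs, link_type = "synthesizing", reaction_id = "R")
  classes <- c(a1 = "anti_predicted", a2 = "anti_predicted",
               w1 = "well_predicted", w2 = "well_predicted")
  res <- adjacency_permutation_test(adj, classes,
                                    null_model_config(n_label_permutations = 200,
                                                      rng_seed = 53))
  expect_equal(unname(res$observed["synthesizing"]), 4L)  # all anti-well pairs
  expect_equal(unname(res$p_values["total"]), 1)
})

test_that("adjacency permutation p matches exhaustive label enumeration", {
  set.seed(54)
  nodes <- paste0("n", 1:6)
  adj <- data.frame(met_u = c("n1", "n2", "n3", "n4", "n1"),
                    met_v = c("n2", "n3", "n4", "n5", "n6"),
                    link_type = "synthesizing", reaction_id = paste0("R", 1:5),
                    stringsAsFactors = FALSE)
  classes <- c(n1 = "well_predicted", n2 = "anti_predicted",
               n3 = "well_predicted", n4 = "not_significant",
               n5 = "anti_predicted", n6 = "not_significant")

  count_total <- function(lab) {
    hit <- lab[adj$met_u] == "well_predicted" & lab[adj$met_v] == "anti_predicted"
    length(unique(paste(pmin(adj$met_u[hit], adj$met_v[hit]),
                        pmax(adj$met_u[hit], adj$met_v[hit]))))
  }
  obs <- count_total(classes)
  P <- all_perms(seq_along(nodes))
  counts <- apply(P, 1, function(p) {
    count_total(setNames(unname(classes)[p], nodes))
  })
  p_exact <- mean(counts >= obs)

  np <- 1500
  res <- adjacency_permutation_test(adj, classes,
                                    null_model_config(n_label_permutations = np,
                                                      rng_seed = 55))
  se <- sqrt(p_exact * (1 - p_exact) / np)
  expect_lt(abs(res$p_values["total"] - p_exact), 3 * se + 1 / (np + 1))
})

test_that("network null test reports a valid empirical p and excludes failures", {
  fx <- generate_fixture(fixture_spec(n_metabolites = 10, n_genes = 100,
                                      n_samples = 10, rng_seed = 56))
  nt <- network_null_test(fx$model, fx$gene_abundance, fx$metabolites,
                          prediction_config(n_permutations = 199),
                          null_model_config(n_random_networks = 3,
                                            n_edge_swaps = 500, rng_seed = 57))
  expect_gte(nt$p_value, 1 / (nt$n_replicates + 1))
  expect_lte(nt$p_value, 1)
  expect_equal(nt$n_replicates + nt$n_failed, 3L)
})
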