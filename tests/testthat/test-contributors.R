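test_that("single-taxon communities make that taxon key for every varying metabolite", {
  fx <- generate_fixture(fixture_spec(n_taxa = 1, n_metabolites = 8,
                                      n_genes = 90, n_samples = 8,
                                      taxon_zero_prob = 0, rng_seed = 41))
  ks <- key_species(fx$model, fx$taxa, fx$genomes)
  cmp <- fx$cmp
  varying <- rownames(cmp)[apply(cmp, 1, sd) > 0]
  hit <- ks[ks$metabolite %in% varying, ]
  expect_true(all(hit$is_key))
  expect_true(all(abs(hit$correlation - 1) < 1e-12))
})

test_that("taxa with no genes touching a metabolite are never key for it", {
  # two taxa; t2 carries no gene at all
  taxa <- matrix(c(1, 3, 2, 5, 4, 1, 2, 0), 2, 4, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), paste0("s", 1:4)))
  genomes <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                    dimnames = list(c("t1", "t2"), c("g1", "g2")))
  m <- chain_model()
  ks <- key_species(m, taxa, genomes)
  t2 <- ks[ks$taxon == "t2", ]
  expect_true(all(is.na(t2$correlation)))
  expect_false(any(t2$is_key))
  # B's CMP is identically zero here (g1 produces what g2 consumes at equal
  # abundance), so only the varying rows A and C can have key species
  expect_true(all(ks$is_key[ks$taxon == "t1" & ks$metabolite != "B"]))
})

test_that("planted generating taxa are recovered as key species", {
  fx <- generate_fixture(fixture_spec(rng_seed = 42))
  ks <- key_species(fx$model, fx$taxa, fx$genomes)
  ev <- evaluate_key_species(fx$truth, ks)
  expect_gte(ev$precision, 0.9)
  expect_gte(ev$recall, 0.9)
})

test_that("single-link genes are key; redundant equal-profile genes are not", {
  # metabolite B touched by exactly one gene: zeroing destroys the row
  m <- chain_model()
  G <- matrix(c(1, 5, 2, 3, 4, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  kg <- key_genes(m, G)
  expect_true(kg$is_key[kg$metabolite == "A" & kg$gene == "g1"])
  expect_true(is.na(kg$correlation[kg$metabolite == "A" & kg$gene == "g1"]))

  # two genes with identical abundance profiles and equal weights: the
  # perturbed row is half the original, correlation stays 1, neither key
  entries <- parse_reaction_map(c("R1: 00010: A => B", "R2: 00020: A => B"))
  m2 <- build_model(entries, data.frame(gene = c("ga", "gb"),
                                        reaction = c("R1", "R2")))
  G2 <- matrix(rep(c(1, 4, 2, 7), 2), 2, 4, byrow = TRUE,
               dimnames = list(c("ga", "gb"), paste0("s", 1:4)))
  kg2 <- key_genes(m2, G2)
  b_rows <- kg2[kg2$metabolite == "B", ]
  expect_false(any(b_rows$is_key))
  expect_true(all(abs(b_rows$correlation - 1) < 1e-12))
})

test_that("key gene calls match a brute-force deletion oracle", {
  set.seed(43)
  for (i in 1:5) {
    rs <- random_reaction_set()
    genes <- rs$model$genes
    G <- matrix(runif(length(genes) * 6, 0, 5), length(genes), 6,
                dimnames = list(genes, paste0("s", 1:6)))
    kg <- key_genes(rs$model, G)
    M <- rs$model$matrix
    for (k in seq_len(nrow(kg))) {
      M2 <- M
      M2[kg$metabolite[k], kg$gene[k]] <- 0
      orig <- as.numeric(M[kg$metabolite[k], , drop = FALSE] %*% G)
      pert <- as.numeric(M2[kg$metabolite[k], , drop = FALSE] %*% G)
      r <- suppressWarnings(cor(orig, pert))
      expect_equal(kg$is_key[k], is.na(r) || r < 0.5)
    }
  }
})

test_that("key gene calls are invariant to rescaling G", {
  set.seed(44)
  rs <- random_reaction_set()
  genes <- rs$model$genes
  G <- matrix(runif(length(genes) * 5, 0, 5), length(genes), 5,
              dimnames = list(genes, paste0("s", 1:5)))
  expect_equal(key_genes(rs$model, G), key_genes(rs$model, 13 * G))
})

test_that("drive classification follows key reaction roles", {
  kr <- data.frame(metabolite = c("m1", "m2", "m3", "m3"),
                   reaction_id = c("R1", "R2", "R3", "R4"),
                   role = c("produces", "consumes", "produces", "consumes"),
                   gene = "g")
  drive <- classify_drive(kr, metabolites = c("m1", "m2", "m3", "m4"))
  expect_equal(unname(drive["m1"]), "synthesis")
  expect_equal(unname(drive["m2"]), "degradation")
  expect_equal(unname(drive["m3"]), "mixed")
  expect_equal(unname(drive["m4"]), "none")
})

test_that("key reactions derive only from key genes via provenance", {
  m <- chain_model()
  G <- matrix(c(1, 5, 2, 3, 4, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  rep <- contributor_report(m, G = G)
  expect_true(all(rep$reactions$gene %in% rep$genes$gene[rep$genes$is_key]))
  # B is produced by R1 and consumed by R2; when both genes are key its
  # drive is mixed
  if (all(c("g1", "g2") %in% rep$reactions$gene[rep$reactions$metabolite == "B"])) {
    expect_equal(unname(rep$drive["B"]), "mixed")
  }
  expect_true(all(names(rep$drive) == m$metabolites))
})
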