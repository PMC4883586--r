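test_that("mapformula parsing normalizes direction and applies coefficients", {
  e <- parse_reaction_map("R1: 00010: A => B")[[1]]
  expect_equal(e$reaction_id, "R1")
  expect_equal(e$pathway_id, "00010")
  expect_equal(e$substrates$compound, "A")
  expect_equal(e$products$compound, "B")
  expect_equal(e$direction, "forward")

  # reverse lines are stored side-swapped as forward
  e <- parse_reaction_map("R2: 00020: A <= B")[[1]]
  expect_equal(e$substrates$compound, "B")
  expect_equal(e$products$compound, "A")
  expect_equal(e$direction, "forward")

  coefs <- data.frame(reaction_id = "R3",
                      compound_id = c("A", "B", "C"),
                      coefficient = c(1, 2, 1))
  e <- parse_reaction_map("R3: 00030: A + B <=> C", coefficients = coefs)[[1]]
  expect_equal(e$direction, "reversible")
  expect_equal(e$substrates$compound, c("A", "B"))
  expect_equal(e$substrates$coefficient, c(1, 2))
  expect_equal(e$products$coefficient, 1)
})

test_that("parser skips malformed lines with a warning and rejects bad input", {
  expect_warning(
    entries <- parse_reaction_map(c("R1: 00010: A => B",
                                    "not a reaction line",
                                    "R2: 00010: A => A")),  # shared compound
    "malformed")
  expect_length(entries, 1)
  expect_equal(attr(entries, "n_skipped"), 2L)

  expect_error(parse_reaction_map(character(0)), "empty")
  expect_error(parse_reaction_map("   "), "empty")

  bad_coef <- data.frame(reaction_id = "R1", compound_id = "ZZZ", coefficient = 2)
  expect_error(parse_reaction_map("R1: 00010: A => B", coefficients = bad_coef),
               "R1")
})

test_that("direction resolution treats any conflict or reversibility as reversible", {
  e <- parse_reaction_map(c("R1: 00010: A => B", "R1: 00020: A => B"))
  expect_equal(resolve_directions(e)$R1$direction, "forward_only")

  e <- parse_reaction_map(c("R2: 00010: A => B", "R2: 00020: B => A"))
  expect_equal(resolve_directions(e)$R2$direction, "reversible")

  e <- parse_reaction_map(c("R3: 00010: A <=> B", "R3: 00020: A => B"))
  expect_equal(resolve_directions(e)$R3$direction, "reversible")
})

test_that("model construction accumulates signed contributions and normalizes rows", {
  m <- chain_model()
  expect_setequal(m$metabolites, c("A", "B", "C"))
  expect_equal(m$matrix["A", c("g1", "g2")], c(g1 = -1, g2 = 0))
  expect_equal(m$matrix["B", c("g1", "g2")], c(g1 = 1, g2 = -1))
  expect_equal(m$matrix["C", c("g1", "g2")], c(g1 = 0, g2 = 1))

  # multi-substrate reaction with a coefficient: row normalization is per
  # metabolite row, so single-entry rows become +/-1
  coefs <- data.frame(reaction_id = "R", compound_id = "B", coefficient = 2)
  entries <- parse_reaction_map("R: 00010: A + B => C", coefficients = coefs)
  mod <- build_model(entries, data.frame(gene = "g1", reaction = "R"))
  expect_equal(mod$raw[, "g1"], c(A = -1, B = -2, C = 1))
  expect_equal(mod$matrix[, "g1"], c(A = -1, B = -1, C = 1))
})

test_that("reversible-only metabolites and empty models are handled", {
  entries <- parse_reaction_map(c("R1: 00010: A => B", "R2: 00010: X <=> Y"))
  gm <- data.frame(gene = c("g1", "g2"), reaction = c("R1", "R2"))
  m <- build_model(entries, gm)
  expect_false(any(c("X", "Y") %in% m$metabolites))
  expect_false("g2" %in% m$genes)

  only_rev <- parse_reaction_map("R2: 00010: X <=> Y")
  expect_error(build_model(only_rev, data.frame(gene = "g2", reaction = "R2")),
               "empty model")
})

test_that("raw matrix matches the naive triple-loop oracle on random inputs", {
  set.seed(401)
  for (i in 1:30) {
    rs <- random_reaction_set()
    naive <- naive_raw_matrix(rs$directions, rs$gene_map)
    expect_equal(rs$model$raw,
                 naive[rownames(rs$model$raw), colnames(rs$model$raw), drop = FALSE],
                 tolerance = 0)
  }
})

test_that("row sign-group sums are exactly +/-1 and input order is irrelevant", {
  set.seed(402)
  for (i in 1:10) {
    rs <- random_reaction_set()
    M <- rs$model$matrix
    for (r in seq_len(nrow(M))) {
      if (any(M[r, ] < 0)) expect_equal(sum(M[r, ][M[r, ] < 0]), -1, tolerance = 1e-9)
      if (any(M[r, ] > 0)) expect_equal(sum(M[r, ][M[r, ] > 0]), 1, tolerance = 1e-9)
    }
    # shuffle input line order: identical matrix up to row/column ordering
    entries2 <- suppressWarnings(
      parse_reaction_map(sample(rs$lines), coefficients = rs$coefficients))
    m2 <- suppressWarnings(build_model(entries2, rs$gene_map))
    expect_setequal(rownames(m2$matrix), rownames(M))
    expect_setequal(colnames(m2$matrix), colnames(M))
    expect_equal(m2$matrix[rownames(M), colnames(M), drop = FALSE], M)
  }
})

test_that("provenance records support every nonzero cell with matching roles", {
  set.seed(403)
  rs <- random_reaction_set()
  m <- rs$model
  nz <- which(m$raw != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    met <- rownames(m$raw)[nz[k, 1]]
    g <- colnames(m$raw)[nz[k, 2]]
    recs <- m$provenance[m$provenance$metabolite == met & m$provenance$gene == g, ]
    expect_gt(nrow(recs), 0)
    role_needed <- if (m$raw[met, g] > 0) "produces" else "consumes"
    expect_true(role_needed %in% recs$role)
  }

  # removing a gene never increases any cell's provenance support
  gm <- as_gene_map(rs$gene_map)
  if (length(gm) > 1) {
    gm_small <- gm[-1]
    m_small <- try(suppressWarnings(
      build_model(rs$entries, gm_small, rs$directions)), silent = TRUE)
    if (!inherits(m_small, "try-error")) {
      count_records <- function(mod) {
        tab <- table(paste(mod$provenance$metabolite, mod$provenance$gene))
        tab
      }
      big <- count_records(m)
      small <- count_records(m_small)
      for (cell in names(small)) {
        expect_lte(small[[cell]], big[[cell]])
      }
    }
  }
})

test_that("metabolite adjacency types links by resolved reaction direction", {
  entries <- parse_reaction_map(c("R1: 00010: A => B", "R2: 00010: C <=> D"))
  gm <- data.frame(gene = c("g1", "g2"), reaction = c("R1", "R2"))
  m <- build_model(entries, gm)
  adj <- metabolite_adjacency(m)

  has <- function(u, v, tp) {
    any(adj$met_u == u & adj$met_v == v & adj$link_type == tp)
  }
  expect_true(has("A", "B", "synthesizing"))
  expect_true(has("B", "A", "depleting"))
  expect_true(has("C", "D", "reversible"))
  expect_true(has("D", "C", "reversible"))
  # no shared reaction, no record
  expect_false(any(adj$met_u == "A" & adj$met_v == "C"))
})
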