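# Independent brute-force oracles kept deliberately naive: they re-derive
# quantities with plain loops/enumeration, never by calling the code paths
# they check.

# Accumulate the raw (pre-normalization) impact matrix over every
# (gene, reaction, compound) triple, forward_only reactions only.
naive_raw_matrix <- function(directions, gene_map) {
  gene_map <- as_gene_map(gene_map)
  mets <- character(0); genes <- character(0)
  vals <- list()
  for (g in names(gene_map)) {
    for (r in gene_map[[g]]) {
      d <- directions[[r]]
      if (is.null(d) || d$direction != "forward_only") next
      for (k in seq_len(nrow(d$substrates))) {
        vals[[length(vals) + 1]] <- list(m = d$substrates$compound[k], g = g,
                                         v = -d$substrates$coefficient[k])
      }
      for (k in seq_len(nrow(d$products))) {
        vals[[length(vals) + 1]] <- list(m = d$products$compound[k], g = g,
                                         v = d$products$coefficient[k])
      }
    }
  }
  mets <- sort(unique(vapply(vals, `[[`, "", "m")))
  genes <- sort(unique(vapply(vals, `[[`, "", "g")))
  M <- matrix(0, length(mets), length(genes), dimnames = list(mets, genes))
  for (cell in vals) M[cell$m, cell$g] <- M[cell$m, cell$g] + cell$v
  M
}

# Entrywise triple-loop matrix product.
naive_cmp <- function(M, G) {
  genes <- intersect(colnames(M), rownames(G))
  out <- matrix(0, nrow(M), ncol(G), dimnames = list(rownames(M), colnames(G)))
  for (m in rownames(M)) {
    for (s in colnames(G)) {
      acc <- 0
      for (g in genes) acc <- acc + M[m, g] * G[g, s]
      out[m, s] <- acc
    }
  }
  out
}

# All permutations of a vector, one per row.
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, 1L))
  out <- NULL
  for (k in seq_len(n)) {
    sub <- all_perms(v[-k])
    out <- rbind(out, cbind(v[k], sub))
  }
  unname(out)
}

# Exhaustive Mantel test: enumerate every sample-label permutation.
exhaustive_mantel <- function(x, y, method = "spearman") {
  n <- length(x)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dx <- x[ut[, 1]] - x[ut[, 2]]
  dy <- y[ut[, 1]] - y[ut[, 2]]
  rho <- cor(dx, dy, method = method)
  P <- all_perms(seq_len(n))
  r <- apply(P, 1, function(p) {
    yp <- y[p]
    cor(dx, yp[ut[, 1]] - yp[ut[, 2]], method = method)
  })
  list(rho = rho,
       p_pos = mean(r >= rho - 1e-12),
       p_neg = mean(r <= rho + 1e-12))
}

# Random small reaction set (<= 8 reactions, <= 6 genes) with integer
# coefficients; regenerates until at least one mapped single-direction
# reaction exists so the model is buildable.
random_reaction_set <- function() {
  repeat {
    n_rxn <- sample(2:8, 1)
    n_gene <- sample(2:6, 1)
    comps <- sprintf("C%02d", 1:8)
    lines <- character(n_rxn)
    rids <- sprintf("R%02d", seq_len(n_rxn))
    coef_rows <- list()
    any_forward <- FALSE
    for (i in seq_len(n_rxn)) {
      k_s <- sample(1:2, 1); k_p <- sample(1:2, 1)
      picked <- sample(comps, k_s + k_p)
      dir_tok <- sample(c("=>", "<=>", "<="), 1, prob = c(0.7, 0.15, 0.15))
      if (dir_tok != "<=>") any_forward <- TRUE
      lines[i] <- sprintf("%s: 00010: %s %s %s", rids[i],
                          paste(picked[seq_len(k_s)], collapse = " + "),
                          dir_tok,
                          paste(picked[-seq_len(k_s)], collapse = " + "))
      if (runif(1) < 0.3) {
        cc <- sample(picked, 1)
        coef_rows[[length(coef_rows) + 1]] <- data.frame(
          reaction_id = rids[i], compound_id = cc,
          coefficient = sample(2:3, 1), stringsAsFactors = FALSE)
      }
    }
    if (!any_forward) next
    genes <- sprintf("K%02d", seq_len(n_gene))
    gene_map <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene = g, reaction = sample(rids, sample(seq_len(min(3L, n_rxn)), 1)),
                 stringsAsFactors = FALSE)
    }))
    coefficients <- if (length(coef_rows)) do.call(rbind, coef_rows) else NULL
    entries <- suppressWarnings(parse_reaction_map(lines, coefficients = coefficients))
    dirs <- resolve_directions(entries)
    model <- try(suppressWarnings(build_model(entries, gene_map, dirs)),
                 silent = TRUE)
    if (!inherits(model, "try-error")) {
      return(list(lines = lines, gene_map = gene_map,
                  coefficients = coefficients, entries = entries,
                  directions = dirs, model = model))
    }
  }
}

# A tiny linear chain model: g1 catalyzes A => B, g2 catalyzes B => C.
chain_model <- function() {
  entries <- parse_reaction_map(c("R1: 00010: A => B",
                                  "R2: 00010: B => C"))
  build_model(entries, data.frame(gene = c("g1", "g2"),
                                  reaction = c("R1", "R2")))
}
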