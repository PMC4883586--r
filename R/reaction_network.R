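#' Parse reaction-direction lines in the KEGG mapformula dialect
#'
#' Each line has the form `RID: PATHID: LHS <dir> RHS` where `<dir>` is one
#' of `=>` (forward), `<=` (reverse), or `<=>` (reversible), and LHS/RHS are
#' `+`-separated compound identifiers. A reaction may appear on several
#' lines, once per pathway context. `<=` lines are normalized by swapping
#' sides, so every stored entry is either forward or reversible.
#'
#' Stoichiometric coefficients are not part of the dialect; they default to
#' 1 and can be overridden per (reaction, compound) with a coefficient
#' table (see [read_coefficients]). Malformed lines (including lines whose
#' two sides share a compound) are skipped with a warning; the skip count is
#' attached as attribute `n_skipped`.
#'
#' @param lines Character vector of lines, a single string with embedded
#'   newlines, or a path to a file.
#' @param coefficients Optional data frame with columns `reaction_id`,
#'   `compound_id`, `coefficient`. An entry naming a compound that never
#'   occurs in the corresponding reaction is an error.
#' @return List of reaction entries (class `reaction_entry`), each with
#'   fields `reaction_id`, `pathway_id`, `substrates`, `products` (data
#'   frames with columns `compound`, `coefficient`), and `direction`
#'   (`"forward"` or `"reversible"`).
#' @export
parse_reaction_map <- function(lines, coefficients = NULL) {
  if (length(lines) == 1L && !grepl("\n", lines, fixed = TRUE) && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  } else if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty reaction input: nothing to parse")

  parse_side <- function(s) {
    comps <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    comps[nzchar(comps)]
  }

  entries <- list()
  n_skipped <- 0L
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*([^:]+):\\s*(.+)$", ln))[[1L]]
    ok <- length(m) == 4L
    if (ok) {
      rid <- trimws(m[2L]); pid <- trimws(m[3L]); eq <- m[4L]
      dir_tok <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
        else if (grepl("=>", eq, fixed = TRUE)) "=>"
        else if (grepl("<=", eq, fixed = TRUE)) "<="
        else NA_character_
      sides <- if (!is.na(dir_tok)) strsplit(eq, dir_tok, fixed = TRUE)[[1L]]
      ok <- !is.na(dir_tok) && length(sides) == 2L
      if (ok) {
        lhs <- parse_side(sides[1L]); rhs <- parse_side(sides[2L])
        ok <- length(lhs) > 0L && length(rhs) > 0L &&
          length(intersect(lhs, rhs)) == 0L
        if (ok) {
          if (dir_tok == "<=") { tmp <- lhs; lhs <- rhs; rhs <- tmp; dir_tok <- "=>" }
          entries[[length(entries) + 1L]] <- structure(list(
            reaction_id = rid,
            pathway_id = pid,
            substrates = data.frame(compound = lhs, coefficient = 1,
                                    stringsAsFactors = FALSE),
            products = data.frame(compound = rhs, coefficient = 1,
                                  stringsAsFactors = FALSE),
            direction = if (dir_tok == "<=>") "reversible" else "forward"
          ), class = "reaction_entry")
        }
      }
    }
    if (!ok) n_skipped <- n_skipped + 1L
  }
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " malformed reaction line(s)")
  }
  if (length(entries) == 0L) stop("no parseable reaction lines in input")

  if (!is.null(coefficients)) {
    entries <- apply_coefficients(entries, coefficients)
  }
  attr(entries, "n_skipped") <- n_skipped
  entries
}

# Override default unit coefficients from a (reaction, compound, coefficient)
# table; error if the table names a compound the reaction never uses.
apply_coefficients <- function(entries, coefficients) {
  rids <- vapply(entries, function(e) e$reaction_id, "")
  for (rid in unique(coefficients$reaction_id)) {
    rows <- coefficients[coefficients$reaction_id == rid, , drop = FALSE]
    hit <- which(rids == rid)
    if (length(hit) == 0L) next
    known <- unique(unlist(lapply(entries[hit], function(e) {
      c(e$substrates$compound, e$products$compound)
    })))
    bad <- setdiff(rows$compound_id, known)
    if (length(bad) > 0L) {
      stop("coefficient table references unknown compound(s) ",
           paste(bad, collapse = ", "), " for reaction ", rid)
    }
    for (k in hit) {
      for (side in c("substrates", "products")) {
        tab <- entries[[k]][[side]]
        idx <- match(tab$compound, rows$compound_id)
        tab$coefficient[!is.na(idx)] <- rows$coefficient[idx[!is.na(idx)]]
        entries[[k]][[side]] <- tab
      }
    }
  }
  entries
}

#' Resolve per-reaction directionality across pathway contexts
#'
#' A reaction that appears with one consistent direction in every pathway
#' context is `forward_only`, with canonical substrate/product sides taken
#' as the union across contexts. A reaction annotated as reversible
#' anywhere, or written in conflicting directions across contexts (some
#' compound appears as a substrate in one context and a product in
#' another), is `reversible`.
#'
#' @param entries List of reaction entries from [parse_reaction_map].
#' @return Named list, one element per reaction ID, each with `direction`
#'   (`"forward_only"` or `"reversible"`), `substrates`, and `products`
#'   (data frames of compound/coefficient, canonical orientation).
#' @export
resolve_directions <- function(entries) {
  if (length(entries) == 0L) stop("no reaction entries supplied")
  rids <- vapply(entries, function(e) e$reaction_id, "")

  merge_side <- function(es, side) {
    tab <- do.call(rbind, lapply(es, function(e) e[[side]]))
    tab[!duplicated(tab$compound), , drop = FALSE]
  }

  out <- list()
  for (rid in unique(rids)) {
    es <- entries[rids == rid]
    any_rev <- any(vapply(es, function(e) e$direction == "reversible", NA))
    fw <- es[vapply(es, function(e) e$direction == "forward", NA)]
    subs <- if (length(fw)) merge_side(fw, "substrates") else merge_side(es, "substrates")
    prods <- if (length(fw)) merge_side(fw, "products") else merge_side(es, "products")
    conflict <- length(intersect(subs$compound, prods$compound)) > 0L
    out[[rid]] <- list(
      direction = if (any_rev || conflict) "reversible" else "forward_only",
      substrates = subs,
      products = prods
    )
  }
  out
}

#' Filtering configuration for stoichiometric model construction
#'
#' @param currency_gene_cutoff Metabolites whose (direction-filtered)
#'   reactions associate with this many or more distinct genes are treated
#'   as ubiquitous "currency" compounds (cofactor-like) and removed.
#'   Default 30.
#' @param drop_reversible Drop reactions resolved as reversible. Reversible
#'   reactions carry no directional information and cannot contribute a sign
#'   to the impact matrix; keeping them (FALSE) scores them in their written
#'   orientation and is intended only for sensitivity exploration.
#' @return A `network_filter_config` list.
#' @export
network_filter_config <- function(currency_gene_cutoff = 30L, drop_reversible = TRUE) {
  currency_gene_cutoff <- as.integer(currency_gene_cutoff)
  stopifnot(currency_gene_cutoff >= 1L, is.logical(drop_reversible))
  structure(list(currency_gene_cutoff = currency_gene_cutoff,
                 drop_reversible = drop_reversible),
            class = "network_filter_config")
}

#' Build the normalized signed stoichiometric impact matrix
#'
#' Constructs the metabolite-by-gene matrix M at the core of CMP scoring.
#' For every gene x and every single-direction reaction it is mapped to,
#' each substrate A with coefficient c contributes -c to the raw cell
#' M\[A, x\] and each product B with coefficient d contributes +d to
#' M\[B, x\], accumulated over reactions. Reversible reactions contribute
#' nothing (under the default filter). Filters are applied in order:
#' directionality, then currency-metabolite removal, then pruning of
#' all-zero rows and columns, and finally per-row sign normalization so
#' that negative entries sum to -1 and positive entries sum to +1.
#'
#' @param entries Reaction entries from [parse_reaction_map].
#' @param gene_map Gene-to-reaction mapping (named list or two-column data
#'   frame; see [as_gene_map]).
#' @param directions Resolved directions from [resolve_directions];
#'   computed from `entries` if omitted.
#' @param cfg A [network_filter_config].
#' @return A `stoich_model` object: list with `matrix` (normalized M),
#'   `raw` (pre-normalization M over the same rows/columns), `metabolites`,
#'   `genes`, `provenance` (data frame: metabolite, gene, reaction_id, role
#'   produces/consumes, coefficient), `currency_removed`, `gene_map`, and
#'   `directions`.
#' @export
build_model <- function(entries, gene_map, directions = resolve_directions(entries),
                        cfg = network_filter_config()) {
  gene_map <- as_gene_map(gene_map)

  usable_dir <- if (cfg$drop_reversible) {
    names(directions)[vapply(directions, function(d) d$direction == "forward_only", NA)]
  } else {
    names(directions)
  }
  mapped <- unique(unlist(gene_map, use.names = FALSE))
  usable <- intersect(usable_dir, mapped)
  if (length(usable) == 0L) {
    stop("gene map references no single-direction reaction; empty model")
  }

  compounds <- unique(unlist(lapply(directions[usable], function(d) {
    c(d$substrates$compound, d$products$compound)
  })))
  genes <- names(gene_map)[vapply(gene_map, function(r) any(r %in% usable), NA)]

  raw <- matrix(0, length(compounds), length(genes),
                dimnames = list(compounds, genes))
  prov <- vector("list", 0L)
  for (g in genes) {
    for (r in intersect(gene_map[[g]], usable)) {
      d <- directions[[r]]
      s <- d$substrates; p <- d$products
      raw[s$compound, g] <- raw[s$compound, g] - s$coefficient
      raw[p$compound, g] <- raw[p$compound, g] + p$coefficient
      prov[[length(prov) + 1L]] <- data.frame(
        metabolite = c(s$compound, p$compound),
        gene = g,
        reaction_id = r,
        role = rep(c("consumes", "produces"), c(nrow(s), nrow(p))),
        coefficient = c(s$coefficient, p$coefficient),
        stringsAsFactors = FALSE
      )
    }
  }
  prov <- do.call(rbind, prov)

  # currency filter: count distinct genes associated (via the gene map) with
  # any surviving reaction touching the metabolite
  rxn_genes <- lapply(usable, function(r) {
    genes[vapply(gene_map[genes], function(v) r %in% v, NA)]
  })
  names(rxn_genes) <- usable
  met_rxns <- lapply(usable, function(r) {
    d <- directions[[r]]
    c(d$substrates$compound, d$products$compound)
  })
  gene_count <- integer(length(compounds))
  names(gene_count) <- compounds
  for (m in compounds) {
    touching <- usable[vapply(met_rxns, function(cs) m %in% cs, NA)]
    gene_count[m] <- length(unique(unlist(rxn_genes[touching])))
  }
  currency <- compounds[gene_count >= cfg$currency_gene_cutoff]
  keep <- setdiff(compounds, currency)
  raw <- raw[keep, , drop = FALSE]

  # prune all-zero rows (e.g., contributions that cancel) and columns
  raw <- raw[rowSums(raw != 0) > 0L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("empty model: all metabolite rows were filtered out")
  raw <- raw[, colSums(raw != 0) > 0L, drop = FALSE]

  M <- normalize_rows(raw)
  prov <- prov[prov$metabolite %in% rownames(raw) & prov$gene %in% colnames(raw), , drop = FALSE]
  prov <- prov[raw[cbind(prov$metabolite, prov$gene)] != 0, , drop = FALSE]
  rownames(prov) <- NULL

  structure(list(
    matrix = M,
    raw = raw,
    metabolites = rownames(M),
    genes = colnames(M),
    provenance = prov,
    currency_removed = currency,
    gene_map = gene_map,
    directions = directions
  ), class = "stoich_model")
}

# Scale each row so negative entries sum to -1 and positive entries to +1.
normalize_rows <- function(raw) {
  M <- raw
  for (i in seq_len(nrow(M))) {
    neg <- M[i, ] < 0
    pos <- M[i, ] > 0
    if (any(neg)) M[i, neg] <- M[i, neg] / sum(abs(M[i, neg]))
    if (any(pos)) M[i, pos] <- M[i, pos] / sum(M[i, pos])
  }
  M
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric impact model:", length(x$metabolites), "metabolites x",
      length(x$genes), "genes\n")
  cat("  nonzero cells:", sum(x$matrix != 0),
      "| currency metabolites removed:", length(x$currency_removed), "\n")
  invisible(x)
}

#' Serialize a stoichiometric model to TSV files
#'
#' Writes the normalized matrix (rows = compound IDs, columns = KO IDs) and
#' the per-cell reaction provenance.
#'
#' @param model A `stoich_model`.
#' @param matrix_path,provenance_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_model <- function(model, matrix_path, provenance_path = NULL) {
  write_feature_table(model$matrix, matrix_path, id_label = "compound_id")
  if (!is.null(provenance_path)) {
    utils::write.table(model$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Metabolite adjacency implied by shared reactions
#'
#' Derives typed metabolite-metabolite links from resolved reactions for
#' the label-permutation adjacency test. For a single-direction reaction,
#' every (substrate u, product v) pair yields a record `(u, v,
#' "synthesizing")` (v is synthesized from u) and its mirror `(v, u,
#' "depleting")` (u is consumed, yielding v). Reversible reactions yield
#' `"reversible"` records in both orientations. Only reactions mapped to at
#' least one gene are considered.
#'
#' @param model A `stoich_model` (supplies the gene map and directions).
#' @param directions Optional resolved directions; defaults to the model's.
#' @return Data frame with columns `met_u`, `met_v`, `link_type`
#'   (`synthesizing`, `depleting`, `reversible`), and `reaction_id`.
#' @export
metabolite_adjacency <- function(model, directions = model$directions) {
  mapped <- unique(unlist(model$gene_map, use.names = FALSE))
  rids <- intersect(names(directions), mapped)
  recs <- vector("list", 0L)
  for (r in rids) {
    d <- directions[[r]]
    subs <- d$substrates$compound
    prods <- d$products$compound
    pairs <- expand.grid(u = subs, v = prods, stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L) next
    if (d$direction == "forward_only") {
      recs[[length(recs) + 1L]] <- data.frame(
        met_u = c(pairs$u, pairs$v),
        met_v = c(pairs$v, pairs$u),
        link_type = rep(c("synthesizing", "depleting"), each = nrow(pairs)),
        reaction_id = r, stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        met_u = c(pairs$u, pairs$v),
        met_v = c(pairs$v, pairs$u),
        link_type = "reversible",
        reaction_id = r, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(met_u = character(), met_v = character(),
                      link_type = character(), reaction_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out[!duplicated(out), , drop = FALSE]
}
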