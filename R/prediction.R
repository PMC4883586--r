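#' Configuration for metabolite prediction testing
#'
#' @param n_permutations Number of sample-label permutations for the Mantel
#'   test (default 10000; at least 99).
#' @param correlation Correlation measure between pair-difference vectors:
#'   `"spearman"` (default) or `"pearson"`.
#' @param p_threshold,q_threshold Significance cutoffs applied jointly to
#'   the empirical Mantel p-value and its FDR q-value (default 0.01 each).
#' @param rng_seed Optional integer seed applied once before the
#'   permutation stream.
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(n_permutations = 10000L,
                              correlation = c("spearman", "pearson"),
                              p_threshold = 0.01, q_threshold = 0.01,
                              rng_seed = NULL) {
  correlation <- match.arg(correlation)
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 99L,
            p_threshold > 0, p_threshold < 1,
            q_threshold > 0, q_threshold < 1)
  structure(list(n_permutations = n_permutations, correlation = correlation,
                 p_threshold = p_threshold, q_threshold = q_threshold,
                 rng_seed = rng_seed),
            class = "prediction_config")
}

#' Signed pairwise differences across samples
#'
#' For a per-sample vector v returns `v[i] - v[j]` over all ordered pairs
#' i < j in the given sample order. Differences are signed (not absolute
#' distances) so that positive and negative coupling between CMP and
#' measured variation remain distinguishable. Pairs with a missing endpoint
#' are NA and flagged via the `pairs` attribute.
#'
#' @param values Numeric per-sample vector (length >= 2).
#' @return Numeric vector of length n(n-1)/2 with attribute `pairs`
#'   (two-column index matrix).
#' @export
pairwise_differences <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 samples to form pairs")
  ut <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  d <- values[ut[, 1L]] - values[ut[, 2L]]
  attr(d, "pairs") <- unname(ut)
  d
}

#' Mantel permutation test for one metabolite
#'
#' Correlates pairwise between-sample differences in CMP scores with
#' pairwise differences in measured abundance, and evaluates significance
#' by permuting sample labels of the measured vector (the permutation unit
#' is the sample, not the pair, respecting the dependence structure among
#' pairs sharing a sample). Samples missing in either vector are excluded
#' before forming pairs.
#'
#' One-sided empirical p-values use the add-one estimator:
#' `p_pos = (#\{rho_perm >= rho_obs\} + 1) / (n_perm + 1)` and analogously
#' `p_neg` for the lower tail, so the smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param x Per-sample CMP score vector.
#' @param y Per-sample measured abundance vector (same samples, same order).
#' @param cfg A [prediction_config].
#' When both vectors carry identical sample names, samples are first put in
#' canonical (alphabetical) order so the sign of each pair difference does
#' not depend on input ordering; unnamed vectors are used as given.
#'
#' @return List with `evaluable`, `rho`, `p_pos`, `p_neg`, `n_samples`,
#'   `n_pairs` (and `reason` when not evaluable: fewer than 3 usable
#'   samples, or a zero-variance difference vector).
#' @export
mantel_test <- function(x, y, cfg = prediction_config()) {
  stopifnot(length(x) == length(y))
  if (!is.null(names(x)) && setequal(names(x), names(y)) &&
      !anyDuplicated(names(x))) {
    ord <- sort(names(x))
    x <- x[ord]
    y <- y[ord]
  }
  not_eval <- function(reason, n) {
    list(evaluable = FALSE, reason = reason, rho = NA_real_,
         p_pos = NA_real_, p_neg = NA_real_, n_samples = n, n_pairs = NA_integer_)
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(not_eval("fewer than 3 usable samples", sum(ok)))
  xu <- x[ok]; yu <- y[ok]
  n <- length(xu)
  ut <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  dx <- xu[ii] - xu[jj]
  dy <- yu[ii] - yu[jj]
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
    return(not_eval("zero-variance difference vector", n))
  }
  spearman <- cfg$correlation == "spearman"
  rho <- stats::cor(dx, dy, method = cfg$correlation)

  np <- cfg$n_permutations
  P <- vapply(seq_len(np), function(k) sample.int(n), integer(n))
  V <- matrix(yu[P], n, np)
  D <- V[ii, , drop = FALSE] - V[jj, , drop = FALSE]
  if (spearman) {
    xv <- rank(dx)
    D <- apply(D, 2L, rank)
  } else {
    xv <- dx
  }
  r <- suppressWarnings(as.vector(stats::cor(xv, D)))
  r[!is.finite(r)] <- 0
  eps <- 1e-12
  list(evaluable = TRUE,
       rho = rho,
       p_pos = (sum(r >= rho - eps) + 1) / (np + 1),
       p_neg = (sum(r <= rho + eps) + 1) / (np + 1),
       n_samples = n,
       n_pairs = length(dx))
}

#' Storey q-values for a vector of p-values
#'
#' Estimates the null proportion pi0 on a lambda grid with spline
#' smoothing (clamped to (0, 1]) and converts p-values to tail-area FDR
#' q-values: `q_i = pi0 * m * p_i / rank_i`, enforced monotone
#' non-decreasing in p. With fewer than 10 p-values the pi0 estimate is
#' unreliable and pi0 = 1 is used (equivalent to Benjamini-Hochberg).
#'
#' @param p Vector of p-values in (0, 1].
#' @param lambda Grid for the pi0 estimate.
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return Vector of q-values, same order as `p`, with attribute `pi0`.
#' @export
compute_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- 1
    if (m < 10L) {
      message("compute_qvalues: fewer than 10 p-values, using pi0 = 1 (Benjamini-Hochberg)")
    } else {
      lam <- lambda[lambda < max(p)]
      if (length(lam) >= 4L) {
        pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1L))
        fit <- try(stats::smooth.spline(lam, pi0_lam, df = 3), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          est <- stats::predict(fit, x = max(lam))$y
          if (is.finite(est)) pi0 <- est
        }
      }
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))
  attr(q, "pi0") <- pi0
  q
}

#' Classify metabolites from Mantel statistics and q-values
#'
#' A metabolite is `well_predicted` when its pair-difference correlation is
#' positive with both the upper-tail Mantel p-value and its q-value below
#' the thresholds; `anti_predicted` when the correlation is negative with
#' the lower-tail p and q below the same thresholds; otherwise
#' `not_significant` (or `not_evaluable` when no statistic could be
#' computed).
#'
#' @param results Data frame with columns `rho`, `p_pos`, `p_neg`, `q_pos`,
#'   `q_neg`.
#' @param cfg A [prediction_config] supplying the thresholds.
#' @return `results` with a `class` column added/replaced.
#' @export
classify_predictions <- function(results, cfg = prediction_config()) {
  cls <- rep("not_significant", nrow(results))
  cls[is.na(results$rho)] <- "not_evaluable"
  well <- !is.na(results$rho) & results$rho > 0 &
    !is.na(results$p_pos) & results$p_pos < cfg$p_threshold &
    !is.na(results$q_pos) & results$q_pos < cfg$q_threshold
  anti <- !is.na(results$rho) & results$rho < 0 &
    !is.na(results$p_neg) & results$p_neg < cfg$p_threshold &
    !is.na(results$q_neg) & results$q_neg < cfg$q_threshold
  cls[well] <- "well_predicted"
  cls[anti] <- "anti_predicted"
  results$class <- cls
  results
}

#' Compare CMP scores with measured metabolite abundances
#'
#' Runs a Mantel permutation test per metabolite shared between the CMP
#' table and the measured metabolite table, corrects the upper- and
#' lower-tail p-value vectors separately with Storey q-values, and
#' classifies each metabolite.
#'
#' @param cmp Metabolites-by-samples CMP matrix from [compute_cmp].
#' @param met Metabolites-by-samples measured abundance matrix (missing
#'   values allowed).
#' @param cfg A [prediction_config].
#' @return Data frame with one row per shared metabolite: `metabolite`,
#'   `rho`, `p_pos`, `p_neg`, `q_pos`, `q_neg`, `n_pairs`, `class`.
#' @export
predict_metabolites <- function(cmp, met, cfg = prediction_config()) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  al <- align_samples(cmp, met)
  cmp <- al$a; met <- al$b
  shared <- intersect(rownames(cmp), rownames(met))
  if (length(shared) == 0L) stop("no metabolites shared between CMP table and metabolite table")
  n_drop <- nrow(met) - length(shared)
  if (n_drop > 0L) {
    message("predict_metabolites: ", n_drop,
            " measured metabolite(s) without CMP scores discarded")
  }
  rows <- lapply(shared, function(m) {
    mt <- mantel_test(cmp[m, ], met[m, ], cfg)
    data.frame(metabolite = m, rho = mt$rho, p_pos = mt$p_pos, p_neg = mt$p_neg,
               n_pairs = if (is.null(mt$n_pairs)) NA_integer_ else mt$n_pairs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_pos <- NA_real_
  res$q_neg <- NA_real_
  ev <- !is.na(res$p_pos)
  if (any(ev)) {
    res$q_pos[ev] <- suppressMessages(compute_qvalues(res$p_pos[ev]))
    res$q_neg[ev] <- suppressMessages(compute_qvalues(res$p_neg[ev]))
  }
  res <- classify_predictions(res, cfg)
  res[, c("metabolite", "rho", "p_pos", "p_neg", "q_pos", "q_neg", "n_pairs", "class")]
}
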