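# Hypergeometric term enrichment with Benjamini-Hochberg FDR, and the
# observed-vs-expected co-occurrence statistic for feature classes in
# syntenic blocks.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (p_(j) * m / j)`, clipped
#' to 1 and returned in the input order (delegates to
#' [stats::p.adjust()], which implements exactly this rule).
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric term enrichment of a gene selection
#'
#' For every term with at least one universe gene, tests whether the
#' selection contains more term-carrying genes than expected by drawing
#' `n = |selection|` genes without replacement from the `M`-gene universe:
#' `p = P(X >= k_obs)` with `X ~ Hypergeometric(M, K_term, n)`
#' (one-sided, enrichment). q-values are BH-adjusted over all tested terms.
#'
#' @param term_map `data.frame` with columns `gene`, `term` (GO-style,
#'   two-column).
#' @param selection Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all genes.
#' @param depletion If `TRUE`, test the lower tail `P(X <= k_obs)` instead.
#' @return `data.frame` sorted by p: `term`, `k` (selected genes with the
#'   term), `n`, `K` (universe genes with the term), `M`, `expected`
#'   (`n * K / M`), `p`, `q`.
#' @export
hypergeom_enrichment <- function(term_map, selection, universe,
                                 depletion = FALSE) {
  selection <- unique(selection)
  universe <- unique(universe)
  if (!all(selection %in% universe)) {
    stop("selection contains genes absent from the universe")
  }
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  tm <- unique(tm[, c("gene", "term")])
  if (nrow(tm) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  M <- length(universe)
  n <- length(selection)
  K_all <- table(tm$term)
  k_sel <- table(factor(tm$term[tm$gene %in% selection],
                        levels = names(K_all)))
  K <- as.integer(K_all)
  k <- as.integer(k_sel)
  p <- if (depletion) {
    stats::phyper(k, K, M - K, n)
  } else {
    stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  }
  out <- data.frame(term = names(K_all), k = k, n = n, K = K, M = M,
                    expected = n * K / M, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed vs expected co-occurrence of two block labels
#'
#' Given `N` syntenic blocks of which `n_A` carry label A and `n_B` carry
#' label B, the independence expectation for blocks carrying both is
#' `n_A * n_B / N` (block-level marginal rates). Significance of the
#' observed overlap uses the hypergeometric upper tail (fixed margins):
#' the probability of at least `observed_both` A-labelled blocks among the
#' `n_B` B-labelled ones.
#'
#' @param block_labels List of per-block label sets (character vectors), or
#'   the `data.frame` returned by [block_stats()] (its comma-separated
#'   `labels` column is split).
#' @param label_a,label_b The two labels (e.g. `"terpene"`, `"defense"`).
#' @return Object of class `cooccurrence`: `N_blocks`, `n_A`, `n_B`,
#'   `observed_both`, `expected_both`, `ratio`, `p`.
#' @export
block_cooccurrence <- function(block_labels, label_a, label_b) {
  if (is.data.frame(block_labels)) {
    block_labels <- strsplit(block_labels$labels, ",", fixed = TRUE)
  }
  N <- length(block_labels)
  if (N == 0L) stop("no blocks")
  has_a <- vapply(block_labels, function(s) label_a %in% s, logical(1))
  has_b <- vapply(block_labels, function(s) label_b %in% s, logical(1))
  n_a <- sum(has_a)
  n_b <- sum(has_b)
  obs <- sum(has_a & has_b)
  expected <- n_a * n_b / N
  structure(list(
    N_blocks = N, n_A = n_a, n_B = n_b,
    observed_both = obs, expected_both = expected,
    ratio = if (expected > 0) obs / expected else NA_real_,
    p = stats::phyper(obs - 1L, n_a, N - n_a, n_b, lower.tail = FALSE)
  ), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("Block label co-occurrence\n")
  cat(sprintf("  %d blocks: %d with A, %d with B\n",
              x$N_blocks, x$n_A, x$n_B))
  cat(sprintf("  observed both: %d  expected under independence: %.2f",
              x$observed_both, x$expected_both))
  if (!is.na(x$ratio)) cat(sprintf("  (ratio %.2f)", x$ratio))
  cat(sprintf("\n  hypergeometric upper-tail p = %.4g\n", x$p))
  invisible(x)
}
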