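# Linkage-map summary statistics, sex-association scanning of markers, and
# putative sex-chromosome nomination.

#' Linkage map summary statistics
#'
#' Definitions (also carried in the returned `notes` so downstream reports
#' are unambiguous): group length = last minus first marker position; total
#' map length = sum of group lengths; mean markers per group =
#' `n_markers / n_groups`; mean inter-marker gap = total length divided by
#' `(n_markers - n_groups)`, i.e. within-group gaps only — the only
#' denominator under which every counted gap is well defined. Published
#' maps sometimes print a larger mean gap, implying a different (unstated)
#' denominator; this summary reports its own definition explicitly.
#'
#' @param map `data.frame` with columns `group`, `marker`, `cM` (positions
#'   non-decreasing within a group); optional `scaffold`, `bp`.
#' @return Object of class `map_summary`: `n_groups`, `n_markers`,
#'   `total_cM`, `mean_markers_per_group`, `mean_gap_cM`, `per_group`
#'   (`data.frame` with group, markers, length, min/max position), `notes`.
#' @examples
#' m <- data.frame(group = "LG1", marker = c("a", "b"), cM = c(0, 10))
#' map_summary(m)$total_cM
#' @export
map_summary <- function(map) {
  stopifnot(all(c("group", "marker", "cM") %in% names(map)),
            nrow(map) >= 1L, all(map$cM >= 0))
  per <- split(map, map$group)
  if (any(vapply(per, nrow, integer(1)) < 1L)) stop("empty linkage group")
  bad <- vapply(per, function(g) any(diff(g$cM) < 0), logical(1))
  if (any(bad)) {
    stop("positions not non-decreasing within group(s): ",
         paste(names(per)[bad], collapse = ", "))
  }
  per_group <- do.call(rbind, lapply(names(per), function(g) {
    x <- per[[g]]$cM
    data.frame(group = g, n_markers = length(x),
               length_cM = max(x) - min(x),
               min_cM = min(x), max_cM = max(x), stringsAsFactors = FALSE)
  }))
  n_groups <- nrow(per_group)
  n_markers <- nrow(map)
  total <- sum(per_group$length_cM)
  gaps <- n_markers - n_groups
  structure(list(
    n_groups = n_groups, n_markers = n_markers, total_cM = total,
    mean_markers_per_group = n_markers / n_groups,
    mean_gap_cM = if (gaps > 0) total / gaps else NA_real_,
    per_group = per_group,
    notes = paste(
      "total_cM = sum over groups of (last - first position);",
      "mean_gap_cM = total_cM / (n_markers - n_groups),",
      "counting within-group gaps only")
  ), class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Linkage map summary\n")
  cat(sprintf("  %d groups, %d markers, %.1f cM total\n",
              x$n_groups, x$n_markers, x$total_cM))
  cat(sprintf("  mean markers/group: %.1f  mean gap: %.3f cM\n",
              x$mean_markers_per_group, x$mean_gap_cM))
  cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Chi-squared scan for sex-associated markers
#'
#' Per marker, a Pearson chi-squared test of independence (no continuity
#' correction) on the genotype-class x sex contingency table; missing calls
#' are excluded and unobserved genotype classes dropped (degrees of freedom
#' adjust accordingly). Markers with a single observed genotype class are
#' uninformative and get `p = 1` by convention. Significance is `p < alpha`
#' on raw p-values by default (matching the usual circos-track convention);
#' `adjust = "BH"` thresholds BH q-values instead.
#'
#' @param pop A `mapping_population`, or a markers x individuals character
#'   matrix of `A`/`H`/`B` codes (`NA` = missing).
#' @param sex Factor/character of `female`/`male` per individual (taken
#'   from `pop` when it is a `mapping_population`).
#' @param scaffold Optional per-marker scaffold assignment (taken from
#'   `pop$markers$scaffold` when available).
#' @param alpha Significance threshold.
#' @param adjust `"none"` (raw p) or `"BH"`.
#' @return Object of class `sex_scan`: `table` (`data.frame` with
#'   `marker_id`, `scaffold`, `statistic`, `df`, `p`, `q`, `significant`,
#'   `uninformative`), `alpha`, `adjust`, `n_significant`,
#'   `scaffold_counts` (significant markers per scaffold).
#' @export
sex_association_scan <- function(pop, sex = NULL, scaffold = NULL,
                                 alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (methods::is(pop, "mapping_population") ||
      (is.list(pop) && !is.null(pop$genotypes))) {
    geno <- pop$genotypes
    if (is.null(sex)) sex <- pop$sex
    if (is.null(scaffold)) scaffold <- pop$markers$scaffold
  } else {
    geno <- pop
  }
  if (is.null(sex)) stop("sex labels required")
  sex <- factor(as.character(sex))
  if (nlevels(sex) != 2L || any(table(sex) < 2L)) {
    stop("need at least 2 individuals of each sex")
  }
  n_mark <- nrow(geno)
  stat <- df <- p <- rep(NA_real_, n_mark)
  uninf <- rep(FALSE, n_mark)
  for (m in seq_len(n_mark)) {
    g <- geno[m, ]
    keep <- !is.na(g)
    tab <- table(genotype = g[keep], sex = droplevels(sex[keep]))
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      uninf[m] <- TRUE
      p[m] <- 1
      stat[m] <- 0
      df[m] <- 0
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat[m] <- unname(ct$statistic)
    df[m] <- unname(ct$parameter)
    p[m] <- ct$p.value
  }
  q <- bh_fdr(p)
  sig <- if (adjust == "BH") q < alpha else p < alpha
  sig <- sig & !uninf
  res <- data.frame(
    marker_id = if (!is.null(rownames(geno))) rownames(geno) else
      sprintf("mk_%05d", seq_len(n_mark)),
    scaffold = if (!is.null(scaffold)) scaffold else NA_character_,
    statistic = stat, df = df, p = p, q = q,
    significant = sig, uninformative = uninf,
    stringsAsFactors = FALSE)
  counts <- if (!is.null(scaffold)) {
    tab <- table(res$scaffold[res$significant])
    data.frame(scaffold = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)[order(-as.integer(tab)), ]
  } else NULL
  structure(list(table = res, alpha = alpha, adjust = adjust,
                 n_significant = sum(sig),
                 scaffold_counts = counts),
            class = "sex_scan")
}

#' @export
print.sex_scan <- function(x, ...) {
  cat(sprintf(
    "Sex-association scan: %d markers, %d significant (%s < %g)\n",
    nrow(x$table), x$n_significant,
    if (x$adjust == "BH") "BH q" else "raw p", x$alpha))
  if (!is.null(x$scaffold_counts) && nrow(x$scaffold_counts)) {
    cat("  significant markers per scaffold:\n")
    print(utils::head(x$scaffold_counts, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Nominate the putative sex chromosome
#'
#' Returns the scaffold carrying the most significant sex-associated
#' markers. Zero significant markers yield an explicit no-call; an exact
#' tie between scaffolds is reported as ambiguous, never broken silently.
#'
#' @param scan A [sex_association_scan()] result.
#' @return Object of class `sex_chromosome_call`: `status`
#'   (`"called"`/`"ambiguous"`/`"no_call"`), `scaffold` (or tied
#'   scaffolds), `count`, `fraction` (of all significant markers).
#' @export
putative_sex_chromosome <- function(scan) {
  counts <- scan$scaffold_counts
  if (is.null(counts)) stop("scan carries no scaffold assignments")
  total <- sum(counts$count)
  if (total == 0L || nrow(counts) == 0L) {
    return(structure(list(status = "no_call", scaffold = NA_character_,
                          count = 0L, fraction = NA_real_),
                     class = "sex_chromosome_call"))
  }
  best <- counts$count == max(counts$count)
  if (sum(best) > 1L) {
    return(structure(list(status = "ambiguous",
                          scaffold = counts$scaffold[best],
                          count = counts$count[which(best)[1L]],
                          fraction = counts$count[which(best)[1L]] / total),
                     class = "sex_chromosome_call"))
  }
  structure(list(status = "called", scaffold = counts$scaffold[best],
                 count = counts$count[best],
                 fraction = counts$count[best] / total),
            class = "sex_chromosome_call")
}

#' @export
print.sex_chromosome_call <- function(x, ...) {
  switch(x$status,
    no_call = cat("No significant sex-associated markers: no call.\n"),
    ambiguous = cat("Ambiguous: scaffolds",
                    paste(x$scaffold, collapse = ", "),
                    "tie with", x$count, "significant markers each.\n"),
    called = cat(sprintf(
      "Putative sex chromosome: %s (%d significant markers, %.1f%% of all)\n",
      x$scaffold, x$count, 100 * x$fraction)))
  invisible(x)
}

#' Segregation-distortion QC for mapping-population markers
#'
#' Goodness-of-fit chi-squared tests against the expected test-cross (1:1,
#' classes A/H) or F2 (1:2:1, classes A/H/B) segregation; markers whose
#' observed classes match neither layout are flagged `unclassified`.
#' Intended as a marker-QC flag ahead of map construction, not as map
#' estimation.
#'
#' @param pop A `mapping_population` or genotype matrix.
#' @param alpha Distortion flag threshold on the goodness-of-fit p-value.
#' @return `data.frame`: `marker_id`, `model` (`testcross`/`f2`/
#'   `unclassified`), `p`, `distorted`.
#' @export
segregation_qc <- function(pop, alpha = 0.05) {
  geno <- if (is.matrix(pop)) pop else pop$genotypes
  rows <- lapply(seq_len(nrow(geno)), function(m) {
    g <- geno[m, ]
    g <- g[!is.na(g)]
    obs <- table(factor(g, levels = c("A", "H", "B")))
    has_b <- obs[["B"]] > 0L
    if (has_b) {
      p <- stats::chisq.test(as.integer(obs),
                             p = c(0.25, 0.5, 0.25))$p.value
      model <- "f2"
    } else if (obs[["A"]] > 0L && obs[["H"]] > 0L) {
      p <- stats::chisq.test(as.integer(obs[c("A", "H")]),
                             p = c(0.5, 0.5))$p.value
      model <- "testcross"
    } else {
      p <- NA_real_
      model <- "unclassified"
    }
    data.frame(marker_id = rownames(geno)[m] %||% sprintf("mk_%05d", m),
               model = model, p = p,
               distorted = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
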