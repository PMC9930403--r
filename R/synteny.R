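# Collinear syntenic blocks: MCScanX-style .collinearity parsing/writing,
# a simplified dynamic-programming block detector, and per-block content
# statistics.

#' Synteny detection parameters
#'
#' `min_anchors = 5` matches a default-settings MCScanX run; the
#' visualisation-oriented preset (`synteny_config(min_anchors = 10)`)
#' corresponds to a MATCH_SIZE of nine, i.e. at least 10 anchor genes per
#' block. `max_gap` is the largest allowed rank gap (gene-index units)
#' between consecutive anchors on either axis.
#'
#' @param min_anchors Minimum anchors per block (>= 2).
#' @param max_gap Maximum rank gap between consecutive anchors.
#' @param collapse_tandem Collapse runs of rank-consecutive genes of the
#'   same family (requires a `family` column) to the first member before
#'   chaining.
#' @return List of class `synteny_config`.
#' @export
synteny_config <- function(min_anchors = 5L, max_gap = 25L,
                           collapse_tandem = TRUE) {
  stopifnot(min_anchors >= 2L, max_gap >= 1L)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 collapse_tandem = isTRUE(collapse_tandem)),
            class = "synteny_config")
}

.empty_blocks <- function() {
  structure(list(), class = "synteny_blocks")
}

new_block <- function(id, scaffold_a, scaffold_b, orientation, anchors,
                      score = NA_real_, e_value = NA_real_) {
  list(id = id, scaffold_a = scaffold_a, scaffold_b = scaffold_b,
       orientation = orientation, score = score, e_value = e_value,
       anchors = anchors)
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(length(x), "syntenic block(s)\n")
  for (b in utils::head(x, 5L)) {
    cat(sprintf("  %s: %s ~ %s  %s, %d anchors\n", b$id, b$scaffold_a,
                b$scaffold_b, b$orientation, nrow(b$anchors)))
  }
  if (length(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Parse an MCScanX-style .collinearity file
#'
#' Accepts the MCScanX dialect: `## Alignment n: score=... e_value=... N=...
#' chrA&chrB plus|minus` headers, each followed by exactly N anchor lines
#' (`n-k: geneA geneB e-value`); other `#` lines are comments. An anchor
#' count that disagrees with the header `N` is a hard parse error reported
#' with the offending line number.
#'
#' @param path Input file.
#' @return Object of class `synteny_blocks` (list of blocks; each block has
#'   `id`, `scaffold_a`, `scaffold_b`, `orientation` (`same`/`inverted`),
#'   `score`, `e_value`, and an `anchors` data.frame with `gene_a`,
#'   `gene_b`, `e_value`).
#' @export
parse_collinearity <- function(path) {
  lines <- readLines(path, warn = FALSE)
  head_re <- paste0("^##\\s*Alignment\\s+(\\S+):\\s*score=(\\S+)\\s+",
                    "e_value=(\\S+)\\s+N=(\\d+)\\s+(\\S+)&(\\S+)\\s+",
                    "(plus|minus)\\s*$")
  blocks <- list()
  cur <- NULL
  cur_n <- 0L
  cur_line <- 0L
  anchors <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (length(anchors) != cur_n) {
      stop("alignment header at line ", cur_line, " announces N=", cur_n,
           " anchors but ", length(anchors), " anchor lines follow")
    }
    cur$anchors <- do.call(rbind, anchors)
    blocks[[length(blocks) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec(head_re, ln))[[1L]]
    if (length(m)) {
      flush()
      anchors <- list()
      cur_n <- as.integer(m[5L])
      cur_line <- i
      cur <- new_block(
        id = m[2L], scaffold_a = m[6L], scaffold_b = m[7L],
        orientation = if (m[8L] == "plus") "same" else "inverted",
        anchors = NULL,
        score = as.numeric(m[3L]), e_value = as.numeric(m[4L]))
      next
    }
    if (grepl("^\\s*#", ln) || !nzchar(trimws(ln))) next
    if (is.null(cur)) stop("anchor line ", i, " before any alignment header")
    # anchor prefixes may be space-padded ("  0-  1:"), as MCScanX writes
    body <- sub("^\\s*[0-9]+-\\s*[0-9]+:\\s*", "", ln)
    if (identical(body, ln)) body <- sub("^\\s*\\S+:\\s*", "", ln)
    f <- strsplit(trimws(body), "\\s+")[[1L]]
    if (length(f) < 2L) stop("malformed anchor line ", i, ": ", ln)
    anchors[[length(anchors) + 1L]] <- data.frame(
      gene_a = f[1L], gene_b = f[2L],
      e_value = if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L]))
                else NA_real_,
      stringsAsFactors = FALSE)
  }
  flush()
  structure(blocks, class = "synteny_blocks")
}

#' Write blocks in the MCScanX .collinearity dialect
#'
#' Inverse of [parse_collinearity()]; a parse of the written file is
#' semantically identical to the input.
#'
#' @param blocks A `synteny_blocks` object.
#' @param path Output file.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### Parameters ###############", con)
  writeLines("# collinearity written by synteks", con)
  for (b in blocks) {
    writeLines(sprintf("## Alignment %s: score=%s e_value=%s N=%d %s&%s %s",
                       b$id,
                       format(if (is.na(b$score)) 0 else b$score),
                       format(if (is.na(b$e_value)) 0 else b$e_value),
                       nrow(b$anchors), b$scaffold_a, b$scaffold_b,
                       if (b$orientation == "same") "plus" else "minus"),
               con)
    for (k in seq_len(nrow(b$anchors))) {
      ev <- b$anchors$e_value[k]
      writeLines(sprintf("%s-%3d:\t%s\t%s\t%s", b$id, k - 1L,
                         b$anchors$gene_a[k], b$anchors$gene_b[k],
                         format(if (is.na(ev)) 0 else ev)),
                 con)
    }
  }
  invisible(path)
}

# Longest chain of match points, strictly monotone in both rank axes with
# per-step gaps <= max_gap. Returns indices into (ra, rb) in chain order.
chain_dp <- function(ra, rb, max_gap) {
  m <- length(ra)
  if (m == 0L) return(integer(0))
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  f <- rep(1L, m)
  parent <- rep(0L, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rb[j] < rb[i] &&
          ra[i] - ra[j] <= max_gap && rb[i] - rb[j] <= max_gap &&
          f[j] + 1L > f[i]) {
        f[i] <- f[j] + 1L
        parent[i] <- j
      }
    }
  }
  best <- which.max(f)
  chain <- integer(f[best])
  k <- f[best]
  i <- best
  while (i > 0L) {
    chain[k] <- i
    k <- k - 1L
    i <- parent[i]
  }
  ord[chain]
}

.collapse_tandem <- function(genes) {
  if (is.null(genes$family)) return(genes)
  genes <- genes[order(genes$scaffold, genes$rank), , drop = FALSE]
  keep <- rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))[-1L]) {
    if (genes$scaffold[i] == genes$scaffold[i - 1L] &&
        !is.na(genes$family[i]) && !is.na(genes$family[i - 1L]) &&
        genes$family[i] == genes$family[i - 1L] &&
        genes$rank[i] == genes$rank[i - 1L] + 1L) {
      keep[i] <- FALSE
      genes$rank[i] <- genes$rank[i - 1L]  # extend runs
    }
  }
  genes[keep, , drop = FALSE]
}

#' Detect collinear syntenic blocks by dynamic-programming chaining
#'
#' MCScanX-like but simplified: within each scaffold pair, homology match
#' points (gene-rank coordinates) are chained to maximise anchor count,
#' requiring strict monotonicity on both axes (increasing, or decreasing on
#' the second axis for inverted blocks) and per-step rank gaps of at most
#' `max_gap`. Chains are extracted greedily (longest first); each match
#' point joins at most one block; chains shorter than `min_anchors` are
#' discarded. The chain score is the anchor count — no e-value weighting.
#'
#' @param genes_a,genes_b Gene tables with `gene_id`, `scaffold` and either
#'   `rank` (order along the scaffold) or `start` (from which ranks are
#'   derived). May be the same table for within-genome comparison
#'   (self-matches `gene_a == gene_b` are ignored).
#' @param pairs Homology pairs: `data.frame` with `gene_a`, `gene_b` and
#'   optionally `score`.
#' @param config A [synteny_config()].
#' @return A `synteny_blocks` object; anchors are ordered by the first
#'   axis.
#' @export
detect_blocks <- function(genes_a, genes_b, pairs,
                          config = synteny_config()) {
  prep <- function(genes) {
    if (is.null(genes$rank)) {
      genes$rank <- stats::ave(genes$start, genes$scaffold,
                               FUN = function(v) rank(v, ties.method = "first"))
    }
    if (config$collapse_tandem) genes <- .collapse_tandem(genes)
    genes
  }
  ga <- prep(genes_a)
  gb <- prep(genes_b)
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  ok <- !is.na(ia) & !is.na(ib) & pairs$gene_a != pairs$gene_b
  pts <- data.frame(gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
                    scaf_a = ga$scaffold[ia[ok]],
                    scaf_b = gb$scaffold[ib[ok]],
                    ra = ga$rank[ia[ok]], rb = gb$rank[ib[ok]],
                    stringsAsFactors = FALSE)
  blocks <- list()
  bid <- 0L
  for (key in unique(paste(pts$scaf_a, pts$scaf_b, sep = "\r"))) {
    sub <- pts[paste(pts$scaf_a, pts$scaf_b, sep = "\r") == key, ,
               drop = FALSE]
    repeat {
      if (nrow(sub) < config$min_anchors) break
      fwd <- chain_dp(sub$ra, sub$rb, config$max_gap)
      rev_ <- chain_dp(sub$ra, -sub$rb, config$max_gap)
      use_fwd <- length(fwd) >= length(rev_)
      chain <- if (use_fwd) fwd else rev_
      if (length(chain) < config$min_anchors) break
      bid <- bid + 1L
      anch <- sub[chain, , drop = FALSE]
      blocks[[bid]] <- new_block(
        id = as.character(bid),
        scaffold_a = anch$scaf_a[1L], scaffold_b = anch$scaf_b[1L],
        orientation = if (use_fwd) "same" else "inverted",
        anchors = data.frame(gene_a = anch$gene_a, gene_b = anch$gene_b,
                             e_value = NA_real_, rank_a = anch$ra,
                             rank_b = anch$rb, stringsAsFactors = FALSE))
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  structure(blocks, class = "synteny_blocks")
}

.as_repeat_iranges <- function(repeats, zero_based = FALSE) {
  if (methods::is(repeats, "GRanges")) {
    return(split(IRanges::ranges(repeats),
                 as.character(GenomicRanges::seqnames(repeats))))
  }
  st <- if (zero_based) repeats$start + 1L else repeats$start
  split(IRanges::IRanges(st, repeats$end), repeats$scaffold)
}

#' Per-block content statistics
#'
#' For each block: anchor count, base-pair spans on both scaffolds,
#' inter-anchor gap lengths on the first scaffold, the fraction of
#' inter-anchor bases covered by repeat (LTR) intervals (interval union —
#' no double counting), and the set of feature labels carried by member
#' genes.
#'
#' @param blocks A `synteny_blocks` object.
#' @param genes Gene table covering every anchor gene (`gene_id`,
#'   `scaffold`, `start`, `end`). Supply both genomes' genes (row-bound)
#'   for cross-genome blocks.
#' @param repeats Repeat intervals: a `data.frame` with `scaffold`,
#'   `start`, `end` (1-based closed; set `zero_based = TRUE` for raw
#'   BED-convention tables) or a `GRanges` (e.g.
#'   `rtracklayer::import(..., format = "BED")`). `NULL` for none.
#' @param labels Optional `data.frame` with `gene_id`, `label`.
#' @param zero_based Interpret `repeats` start coordinates as 0-based
#'   half-open.
#' @return `data.frame` with one row per block: `block_id`, scaffolds,
#'   `n_anchors`, `span_a_start`, `span_a_end`, `span_b_start`,
#'   `span_b_end`, `gap_bases`, `ltr_bases`, `ltr_fraction`, `labels`
#'   (comma-separated).
#' @export
block_stats <- function(blocks, genes, repeats = NULL, labels = NULL,
                        zero_based = FALSE) {
  rep_by_scaf <- if (is.null(repeats) || NROW(repeats) == 0L) list() else
    .as_repeat_iranges(repeats, zero_based)
  rows <- lapply(blocks, function(b) {
    idx_a <- match(b$anchors$gene_a, genes$gene_id)
    idx_b <- match(b$anchors$gene_b, genes$gene_id)
    if (anyNA(idx_a) || anyNA(idx_b)) {
      stop("block ", b$id, " references gene(s) absent from the gene table")
    }
    sa <- genes[idx_a, , drop = FALSE]
    sb <- genes[idx_b, , drop = FALSE]
    sa <- sa[order(sa$start), , drop = FALSE]
    gap_start <- sa$end[-nrow(sa)] + 1L
    gap_end <- sa$start[-1L] - 1L
    keep <- gap_end >= gap_start
    gaps <- IRanges::IRanges(gap_start[keep], gap_end[keep])
    gap_bases <- sum(IRanges::width(gaps))
    ltr_bases <- 0L
    rr <- rep_by_scaf[[b$scaffold_a]]
    if (!is.null(rr) && length(gaps) > 0L) {
      ltr_bases <- sum(IRanges::width(
        IRanges::intersect(IRanges::reduce(rr), IRanges::reduce(gaps))))
    }
    labs <- character(0)
    if (!is.null(labels)) {
      member <- unique(c(b$anchors$gene_a, b$anchors$gene_b))
      labs <- sort(unique(labels$label[labels$gene_id %in% member]))
    }
    data.frame(block_id = b$id,
               scaffold_a = b$scaffold_a, scaffold_b = b$scaffold_b,
               n_anchors = nrow(b$anchors),
               span_a_start = min(sa$start), span_a_end = max(sa$end),
               span_b_start = min(sb$start), span_b_end = max(sb$end),
               gap_bases = gap_bases, ltr_bases = ltr_bases,
               ltr_fraction = if (gap_bases > 0) ltr_bases / gap_bases else 0,
               labels = paste(labs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(block_id = character(0), scaffold_a = character(0),
                      scaffold_b = character(0), n_anchors = integer(0),
                      span_a_start = integer(0), span_a_end = integer(0),
                      span_b_start = integer(0), span_b_end = integer(0),
                      gap_bases = integer(0), ltr_bases = integer(0),
                      ltr_fraction = numeric(0), labels = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-scaffold counts of labelled genes inside syntenic blocks
#'
#' A gene is counted once per scaffold even when it belongs to several
#' (possibly overlapping) blocks.
#'
#' @param blocks A `synteny_blocks` object.
#' @param genes Gene table (`gene_id`, `scaffold`).
#' @param labels `data.frame` with `gene_id`, `label`.
#' @param label The label to count (e.g. `"defense"`).
#' @return `data.frame` (`scaffold`, `count`) sorted by decreasing count.
#' @export
scaffold_feature_counts <- function(blocks, genes, labels, label) {
  member <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))
  lab_genes <- unique(labels$gene_id[labels$label == label])
  hit <- intersect(member, lab_genes)
  scaf <- genes$scaffold[match(hit, genes$gene_id)]
  tab <- table(scaf[!is.na(scaf)])
  out <- data.frame(scaffold = as.character(names(tab)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
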