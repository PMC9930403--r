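# Synthetic two-genome synteny datasets: collinear anchor blocks, tandem
# noise genes, controllable terpene/defense label co-occurrence, and LTR
# intervals in inter-anchor gaps, with a ground-truth block table.

#' Simulate a synteny dataset with known ground truth
#'
#' Builds two gene complements on a few scaffolds each, places `n_blocks`
#' collinear blocks of `anchors_per_block` anchor pairs (random orientation),
#' interleaves non-anchor noise genes, draws per-block terpene/defense
#' labels, and drops LTR intervals into inter-anchor gaps of the first
#' genome at rate `ltr_rate` per gap.
#'
#' Label dependence: with probability `dependence` a block draws both labels
#' from one common uniform variate (comonotone), otherwise independently, so
#' `P(both) = dependence * min(p_terpene, p_defense) +
#' (1 - dependence) * p_terpene * p_defense`, rising monotonically with
#' `dependence`.
#'
#' @param seed Global seed (fixed-offset child stream).
#' @param n_blocks Number of syntenic blocks.
#' @param anchors_per_block Anchor pairs per block.
#' @param ltr_rate Probability that an inter-anchor gap carries an LTR
#'   interval.
#' @param p_terpene,p_defense Per-block label probabilities.
#' @param dependence Label dependence in \[0, 1\] (0 = independent).
#' @param noise_rate Expected non-anchor genes inserted per inter-anchor
#'   position (Poisson).
#' @param n_scaffolds Scaffolds per genome.
#' @param block_spacer_genes Unpaired genes inserted after each block on
#'   both scaffolds, keeping neighbouring blocks on a shared scaffold pair
#'   separated by more than the default chaining gap.
#' @param gene_span,gene_gap Gene length and inter-gene spacing (bp).
#' @return List of class `synteny_sim`: `genes_a`, `genes_b` (gene-level
#'   `data.frame`s: `gene_id`, `scaffold`, `start`, `end`, `strand`, `rank`),
#'   `pairs` (`gene_a`, `gene_b`, `score`), `labels` (`gene_id`, `label`),
#'   `repeats` (`scaffold`, `start`, `end`; 1-based closed), and `truth`
#'   (per-block `data.frame`: `block_id`, scaffolds, orientation,
#'   `n_anchors`, `terpene`, `defense`) plus `anchor_truth` listing the true
#'   anchor pairs per block and `scaffold_label_counts`.
#' @export
simulate_synteny_dataset <- function(seed, n_blocks = 40L,
                                     anchors_per_block = 10L,
                                     ltr_rate = 0.5,
                                     p_terpene = 0.2, p_defense = 0.3,
                                     dependence = 0,
                                     noise_rate = 0.1,
                                     n_scaffolds = 4L,
                                     block_spacer_genes = 30L,
                                     gene_span = 2000L, gene_gap = 3000L) {
  stopifnot(n_blocks >= 1L, anchors_per_block >= 2L,
            ltr_rate >= 0, ltr_rate <= 1,
            p_terpene >= 0, p_terpene <= 1, p_defense >= 0, p_defense <= 1,
            dependence >= 0, dependence <= 1, noise_rate >= 0)
  set.seed(child_seed(seed, "synteny"))

  scafs_a <- sprintf("A_Scaffold_%d", seq_len(n_scaffolds))
  scafs_b <- sprintf("B_Scaffold_%d", seq_len(n_scaffolds))
  block_scaf_a <- sample(scafs_a, n_blocks, replace = TRUE)
  block_scaf_b <- sample(scafs_b, n_blocks, replace = TRUE)
  orientation <- sample(c("same", "inverted"), n_blocks, replace = TRUE)

  # label draws (comonotone-vs-independent mixture copula)
  common <- stats::runif(n_blocks)
  u_t <- stats::runif(n_blocks)
  u_d <- stats::runif(n_blocks)
  use_common <- stats::runif(n_blocks) < dependence
  terp <- ifelse(use_common, common, u_t) < p_terpene
  defe <- ifelse(use_common, common, u_d) < p_defense

  gene_ctr_a <- 0L
  gene_ctr_b <- 0L
  rows_a <- list()
  rows_b <- list()
  pair_rows <- list()
  label_rows <- list()
  repeat_rows <- list()
  anchor_truth <- list()
  # per-scaffold running bp cursor
  cur_a <- stats::setNames(rep(1L, n_scaffolds), scafs_a)
  cur_b <- stats::setNames(rep(1L, n_scaffolds), scafs_b)

  new_gene_a <- function(scaf) {
    gene_ctr_a <<- gene_ctr_a + 1L
    id <- sprintf("ga_%05d", gene_ctr_a)
    st <- cur_a[[scaf]] + gene_gap
    cur_a[[scaf]] <<- st + gene_span
    data.frame(gene_id = id, scaffold = scaf, start = st,
               end = st + gene_span - 1L,
               strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }
  new_gene_b <- function(scaf) {
    gene_ctr_b <<- gene_ctr_b + 1L
    id <- sprintf("gb_%05d", gene_ctr_b)
    st <- cur_b[[scaf]] + gene_gap
    cur_b[[scaf]] <<- st + gene_span
    data.frame(gene_id = id, scaffold = scaf, start = st,
               end = st + gene_span - 1L,
               strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }

  for (b in seq_len(n_blocks)) {
    sa <- block_scaf_a[b]
    sb <- block_scaf_b[b]
    a_genes <- list()
    b_genes <- list()
    for (k in seq_len(anchors_per_block)) {
      # tandem/noise genes between anchors (non-homologous)
      for (dummy in seq_len(stats::rpois(1L, noise_rate))) {
        rows_a[[length(rows_a) + 1L]] <- new_gene_a(sa)
      }
      ga <- new_gene_a(sa)
      gb <- new_gene_b(sb)
      rows_a[[length(rows_a) + 1L]] <- ga
      rows_b[[length(rows_b) + 1L]] <- gb
      a_genes[[k]] <- ga
      b_genes[[k]] <- gb
      # LTR interval in the gap before this anchor (first genome)
      if (k > 1L && stats::runif(1L) < ltr_rate) {
        gap_lo <- a_genes[[k - 1L]]$end + 1L
        gap_hi <- ga$start - 1L
        if (gap_hi > gap_lo) {
          w <- max(1L, floor((gap_hi - gap_lo + 1L) *
                               stats::runif(1L, 0.2, 0.8)))
          st <- gap_lo + sample.int(gap_hi - gap_lo - w + 2L, 1L) - 1L
          repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
            scaffold = sa, start = st, end = st + w - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    # inverted blocks pair a-genes with b-genes in reverse order
    b_ord <- if (orientation[b] == "same") seq_len(anchors_per_block) else
      rev(seq_len(anchors_per_block))
    for (k in seq_len(anchors_per_block)) {
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = a_genes[[k]]$gene_id,
        gene_b = b_genes[[b_ord[k]]]$gene_id,
        score = round(stats::runif(1L, 100, 1000), 1),
        stringsAsFactors = FALSE)
    }
    anchor_truth[[b]] <- data.frame(
      block_id = b,
      gene_a = vapply(a_genes, `[[`, character(1), "gene_id"),
      gene_b = vapply(b_genes[b_ord], `[[`, character(1), "gene_id"),
      stringsAsFactors = FALSE)
    # unpaired spacer genes after each block keep distinct blocks on a
    # shared scaffold pair further apart (in rank units) than any
    # chaining gap, so blocks stay individually recoverable
    for (dummy in seq_len(block_spacer_genes)) {
      rows_a[[length(rows_a) + 1L]] <- new_gene_a(sa)
      rows_b[[length(rows_b) + 1L]] <- new_gene_b(sb)
    }
    # labelled member genes: one labelled a-gene per label present
    if (terp[b]) {
      pick <- sample.int(anchors_per_block, 1L)
      label_rows[[length(label_rows) + 1L]] <- data.frame(
        gene_id = a_genes[[pick]]$gene_id, label = "terpene",
        stringsAsFactors = FALSE)
    }
    if (defe[b]) {
      pick <- sample.int(anchors_per_block, 1L)
      label_rows[[length(label_rows) + 1L]] <- data.frame(
        gene_id = a_genes[[pick]]$gene_id, label = "defense",
        stringsAsFactors = FALSE)
    }
  }

  rank_genes <- function(df) {
    df <- df[order(df$scaffold, df$start), , drop = FALSE]
    df$rank <- stats::ave(seq_len(nrow(df)), df$scaffold,
                          FUN = seq_along)
    rownames(df) <- NULL
    df
  }
  genes_a <- rank_genes(do.call(rbind, rows_a))
  genes_b <- rank_genes(do.call(rbind, rows_b))

  labels <- if (length(label_rows)) do.call(rbind, label_rows) else
    data.frame(gene_id = character(0), label = character(0))
  repeats <- if (length(repeat_rows)) do.call(rbind, repeat_rows) else
    data.frame(scaffold = character(0), start = integer(0),
               end = integer(0))

  truth <- data.frame(block_id = seq_len(n_blocks),
                      scaffold_a = block_scaf_a, scaffold_b = block_scaf_b,
                      orientation = orientation,
                      n_anchors = anchors_per_block,
                      terpene = terp, defense = defe,
                      stringsAsFactors = FALSE)
  lab_per_scaf <- merge(labels,
                        genes_a[, c("gene_id", "scaffold")], by = "gene_id")
  scaffold_label_counts <- as.data.frame(
    table(scaffold = lab_per_scaf$scaffold, label = lab_per_scaf$label),
    stringsAsFactors = FALSE)

  structure(list(genes_a = genes_a, genes_b = genes_b,
                 pairs = do.call(rbind, pair_rows),
                 labels = labels, repeats = repeats,
                 truth = truth,
                 anchor_truth = do.call(rbind, anchor_truth),
                 scaffold_label_counts = scaffold_label_counts),
            class = "synteny_sim")
}
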