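# Synthetic scaffolds with non-overlapping gene models, plus FASTA/GFF3
# writers. Used as plumbing for the annotation and synteny stages.

#' Simulate scaffolds with non-overlapping gene models
#'
#' Draws i.i.d. base composition per scaffold and places non-overlapping,
#' stranded, exon-structured gene models. Deterministic for a fixed seed
#' (byte-identical FASTA/GFF3 output).
#'
#' @param seed Global seed; the generator uses a fixed-offset child stream.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length (bp) of each scaffold (recycled).
#' @param n_genes Total number of genes, distributed round-robin over
#'   scaffolds.
#' @param gene_length_range Min/max gene span (bp).
#' @param n_exons_range Min/max exon count per gene.
#' @param base_freq Named A/C/G/T sampling probabilities.
#' @param out_dir If non-`NULL`, writes `genome.fa` (60-column FASTA) and
#'   `genes.gff3` there.
#' @return List with `scaffolds` (a [Biostrings::DNAStringSet]) and `genes`
#'   (exon-level `data.frame`: `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `source`; 1-based closed coordinates).
#' @examples
#' g <- simulate_genome(seed = 1, scaffold_length = 10000, n_genes = 10)
#' nrow(unique(g$genes[, "gene_id", drop = FALSE]))
#' @export
simulate_genome <- function(seed, n_scaffolds = 1L, scaffold_length = 10000L,
                            n_genes = 10L,
                            gene_length_range = c(300L, 1500L),
                            n_exons_range = c(1L, 4L),
                            base_freq = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                            out_dir = NULL) {
  stopifnot(n_scaffolds >= 1L, n_genes >= 0L,
            all(scaffold_length > 0L),
            abs(sum(base_freq) - 1) < 1e-9, all(base_freq >= 0))
  set.seed(child_seed(seed, "genome"))
  lens <- rep_len(as.integer(scaffold_length), n_scaffolds)
  ids <- sprintf("Scaffold_%d", seq_len(n_scaffolds))

  seqs <- vapply(lens, function(L) {
    paste(sample(names(base_freq), L, replace = TRUE, prob = base_freq),
          collapse = "")
  }, character(1))
  scaffolds <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))

  per_scaf <- tabulate(rep_len(seq_len(n_scaffolds), n_genes), n_scaffolds)
  exon_rows <- list()
  gi <- 0L
  for (s in seq_len(n_scaffolds)) {
    ng <- per_scaf[s]
    if (ng == 0L) next
    glen <- sample(gene_length_range[1]:gene_length_range[2], ng,
                   replace = TRUE)
    spare <- lens[s] - sum(glen)
    if (spare < ng) {
      stop("scaffold ", ids[s], " (", lens[s],
           " bp) is too small for ", ng, " requested genes")
    }
    # distribute the spare bases into ng+1 inter-gene gaps
    gaps <- as.vector(stats::rmultinom(1L, spare, rep(1, ng + 1L)))
    starts <- cumsum(gaps[seq_len(ng)] + c(0L, glen[-ng])) + 1L
    for (g in seq_len(ng)) {
      gi <- gi + 1L
      id <- sprintf("gene_%05d", gi)
      strand <- sample(c("+", "-"), 1L)
      nex <- sample(n_exons_range[1]:n_exons_range[2], 1L)
      nex <- min(nex, max(1L, glen[g] %/% 100L))
      span <- c(starts[g], starts[g] + glen[g] - 1L)
      if (nex == 1L) {
        ex <- cbind(span[1], span[2])
      } else {
        cuts <- sort(sample(seq(span[1] + 1L, span[2] - 1L), 2L * nex - 2L))
        bounds <- c(span[1], cuts, span[2])
        ex <- matrix(bounds, ncol = 2L, byrow = TRUE)
      }
      exon_rows[[gi]] <- data.frame(
        gene_id = id, scaffold = ids[s],
        start = ex[, 1], end = ex[, 2],
        strand = strand, source = "primary_evidence",
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (gi > 0L) do.call(rbind, exon_rows) else
    data.frame(gene_id = character(0), scaffold = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), source = character(0))
  out <- list(scaffolds = scaffolds, genes = genes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(scaffolds, file.path(out_dir, "genome.fa"))
    write_gene_models_gff3(genes, file.path(out_dir, "genes.gff3"))
  }
  out
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a DNAStringSet
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
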