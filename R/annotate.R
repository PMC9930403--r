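# Merging two gene-model sets with source priority, UniProt/Pfam
# classification, and removal of repeat-associated models.
#
# A gene-model set is an exon-level data.frame with columns
# gene_id, scaffold, start, end, strand, source (1-based closed intervals,
# exons of one gene on a single scaffold and strand).

validate_gene_models <- function(genes) {
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("gene model table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$end < genes$start)) stop("exon with end < start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  per_gene <- split(genes, genes$gene_id)
  bad <- vapply(per_gene, function(g) {
    length(unique(g$scaffold)) > 1L || length(unique(g$strand)) > 1L ||
      {
        g <- g[order(g$start), ]
        nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)])
      }
  }, logical(1))
  if (any(bad)) {
    stop("malformed exon structure for gene(s): ",
         paste(utils::head(names(per_gene)[bad], 5L), collapse = ", "))
  }
  invisible(genes)
}

.gene_granges <- function(genes, seqlevels = unique(genes$scaffold)) {
  GenomicRanges::GRanges(
    seqnames = factor(genes$scaffold, levels = seqlevels),
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id)
}

#' Merge two gene-model sets with source priority
#'
#' A secondary (ab initio) model is dropped iff at least `min_overlap` bp of
#' its exons overlap the exons of any primary (expression-evidence) model on
#' the same scaffold and strand; all primary models are retained. This is
#' the usual rule when an expression-based annotation (e.g. from assembled
#' transcripts) takes priority over an ab initio one.
#'
#' @param primary,secondary Exon-level gene-model `data.frame`s (see
#'   [validate_gene_models()] for the required columns).
#' @param min_overlap Minimum exon overlap in bp that triggers a drop
#'   (default 1, the strictest reading).
#' @return Merged exon table sorted by scaffold and coordinate, with a
#'   `source` column (`primary_evidence`/`secondary_abinitio`) and
#'   attribute `dropped` (the dropped secondary gene ids).
#' @export
merge_gene_models <- function(primary, secondary, min_overlap = 1L) {
  validate_gene_models(primary)
  validate_gene_models(secondary)
  primary$source <- "primary_evidence"
  secondary$source <- "secondary_abinitio"
  dropped <- character(0)
  if (nrow(primary) > 0L && nrow(secondary) > 0L) {
    lv <- sort(unique(c(primary$scaffold, secondary$scaffold)))
    gp <- .gene_granges(primary, lv)
    gs <- .gene_granges(secondary, lv)
    hits <- GenomicRanges::findOverlaps(gs, gp,
                                        minoverlap = as.integer(min_overlap),
                                        ignore.strand = FALSE)
    dropped <- unique(gs$gene_id[S4Vectors::queryHits(hits)])
  }
  keep_sec <- secondary[!secondary$gene_id %in% dropped, , drop = FALSE]
  merged <- rbind(primary, keep_sec)
  merged <- merged[order(merged$scaffold, merged$start, merged$end,
                         merged$gene_id), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "dropped") <- dropped
  merged
}

#' Classify genes by UniProt/Pfam annotation support
#'
#' Partitions genes into `both`, `uniprot_only`, `pfam_only`, `neither`
#' according to the databases their annotation hits come from. The
#' partition is exhaustive and mutually exclusive.
#'
#' @param genes Gene-model table (exon- or gene-level; needs `gene_id`,
#'   optionally `scaffold`).
#' @param hits Annotation-hit table with columns `gene`, `db`
#'   (`"uniprot"`/`"pfam"`), `subject`, `pident`, `evalue`, `description`.
#' @param max_evalue Hits above this e-value are ignored (the similarity
#'   threshold; default 1e-5).
#' @return `data.frame` with `gene_id`, `scaffold` (if available) and
#'   `category`; attribute `summary` holds the category counts.
#' @export
classify_annotations <- function(genes, hits, max_evalue = 1e-5) {
  gene_ids <- unique(genes$gene_id)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  has_uni <- gene_ids %in% hits$gene[hits$db == "uniprot"]
  has_pfam <- gene_ids %in% hits$gene[hits$db == "pfam"]
  category <- ifelse(has_uni & has_pfam, "both",
              ifelse(has_uni, "uniprot_only",
              ifelse(has_pfam, "pfam_only", "neither")))
  out <- data.frame(gene_id = gene_ids, category = category,
                    stringsAsFactors = FALSE)
  if ("scaffold" %in% names(genes)) {
    out$scaffold <- genes$scaffold[match(gene_ids, genes$gene_id)]
  }
  attr(out, "summary") <- table(factor(
    category, levels = c("both", "uniprot_only", "pfam_only", "neither")))
  out
}

#' Default repeat-association keywords
#'
#' Read from the package's configuration file
#' (`extdata/repeat_keywords.txt`) rather than being hard-coded.
#'
#' @return Character vector of case-insensitive substrings.
#' @export
repeat_keywords <- function() {
  path <- system.file("extdata", "repeat_keywords.txt", package = "synteks")
  kw <- readLines(path, warn = FALSE)
  kw <- trimws(kw)
  kw[nzchar(kw) & !startsWith(kw, "#")]
}

# Best hit per gene: lowest e-value, ties by higher percent identity, then
# lexicographic subject id.
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$gene, hits$evalue, -hits$pident, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$gene), , drop = FALSE]
}

#' Remove repeat-associated gene models
#'
#' A gene is removed iff the description of its best-ranked annotation hit
#' (lowest e-value; ties by percent identity, then subject id) contains any
#' keyword as a case-insensitive substring. Genes with no hits are kept.
#' The filter is deterministic and idempotent.
#'
#' @param genes Gene-model table (`gene_id` column required).
#' @param hits Annotation-hit table (see [classify_annotations()]).
#' @param keywords Keyword list; defaults to [repeat_keywords()].
#' @return List with `kept` and `removed` (subsets of `genes`) and
#'   `summary` (named counts).
#' @export
filter_repeat_associated <- function(genes, hits,
                                     keywords = repeat_keywords()) {
  if (length(keywords) == 0L) stop("keyword list must be non-empty")
  bh <- best_hits(hits)
  desc <- tolower(bh$description[match(unique(genes$gene_id), bh$gene)])
  flagged <- rep(FALSE, length(desc))
  for (kw in tolower(keywords)) {
    flagged <- flagged | grepl(kw, desc, fixed = TRUE)
  }
  flagged[is.na(desc)] <- FALSE
  removed_ids <- unique(genes$gene_id)[flagged]
  rm_rows <- genes$gene_id %in% removed_ids
  list(kept = genes[!rm_rows, , drop = FALSE],
       removed = genes[rm_rows, , drop = FALSE],
       summary = c(input = length(unique(genes$gene_id)),
                   removed = length(removed_ids),
                   kept = length(unique(genes$gene_id)) -
                     length(removed_ids)))
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene and one `exon` feature per exon
#' (1-based closed coordinates, as GFF3 requires).
#'
#' @param genes Exon-level gene-model table.
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  validate_gene_models(genes)
  per_gene <- split(genes, genes$gene_id)
  gene_rows <- do.call(rbind, lapply(per_gene, function(g) {
    data.frame(gene_id = g$gene_id[1L], scaffold = g$scaffold[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  gr_gene <- GenomicRanges::GRanges(
    gene_rows$scaffold, IRanges::IRanges(gene_rows$start, gene_rows$end),
    strand = gene_rows$strand, type = "gene", ID = gene_rows$gene_id)
  gr_exon <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, type = "exon",
    Parent = genes$gene_id)
  gr <- sort(c(gr_gene, gr_exon))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses exon features (via their `Parent`) when present; features of type
#' `gene` without exon children become single-exon models.
#'
#' @param path GFF3 file.
#' @param source Value for the `source` column of the returned table.
#' @return Exon-level gene-model `data.frame`.
#' @export
read_gene_models_gff3 <- function(path, source = "primary_evidence") {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) > 0L) {
    parent <- vapply(as.list(ex$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
    out <- data.frame(
      gene_id = parent,
      scaffold = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
      strand = as.character(GenomicRanges::strand(ex)),
      source = source, stringsAsFactors = FALSE)
  } else {
    gn <- gr[type == "gene"]
    out <- data.frame(
      gene_id = as.character(gn$ID),
      scaffold = as.character(GenomicRanges::seqnames(gn)),
      start = GenomicRanges::start(gn), end = GenomicRanges::end(gn),
      strand = as.character(GenomicRanges::strand(gn)),
      source = source, stringsAsFactors = FALSE)
  }
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an annotation-hit TSV
#'
#' Expected columns: `gene`, `db`, `subject`, `pident`, `evalue`,
#' `description`.
#'
#' @param path Input TSV.
#' @export
read_annotation_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "db", "subject", "pident", "evalue", "description")
  if (!all(need %in% names(df))) {
    stop("hit table needs columns ", paste(need, collapse = ", "))
  }
  df
}
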