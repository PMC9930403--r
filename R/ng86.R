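# Nei-Gojobori (1986) synonymous/nonsynonymous divergence for codon-aligned
# pairs. Site and pathway tables over the 61 sense codons of the standard
# genetic code are enumerated once per session and cached.

.ng86 <- new.env(parent = emptyenv())

.dna_bases <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons (DNA alphabet).
#' @keywords internal
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.permutations <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Synonymous/nonsynonymous step counts between two codons, averaged over
# mutational pathways. Pathways passing through a stop codon are excluded;
# if every pathway is blocked (possible only for triple differences), all
# pathways are used and stop-passing steps count as nonsynonymous.
.path_counts <- function(c1, c2, gc) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  nd <- length(pos)
  if (nd == 0L) return(c(0, 0))
  walk <- function(ord, allow_stop) {
    cur <- s1
    syn <- 0L
    non <- 0L
    for (p in ord) {
      nxt <- cur
      nxt[p] <- s2[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2 && aa2 != "*") syn <- syn + 1L else non <- non + 1L
      cur <- nxt
    }
    c(syn, non)
  }
  orders <- lapply(.permutations[[nd]], function(o) pos[o])
  res <- lapply(orders, walk, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    res <- lapply(orders, walk, allow_stop = TRUE)
  }
  m <- do.call(rbind, res)
  c(mean(m[, 1]), mean(m[, 2]))
}

#' NG86 codon tables (cached)
#'
#' Builds, once per session, the per-codon synonymous site counts and the
#' 61 x 61 matrices of synonymous/nonsynonymous differences averaged over
#' mutational pathways, plus the synonymous single-step neighbour list used
#' by the sequence-pair generator.
#'
#' @return List with elements `codons`, `sites` (named numeric, synonymous
#'   sites per codon out of 3), `sd`, `nd` (61 x 61 matrices), and
#'   `syn_neighbours` (named list of codons reachable by one synonymous
#'   substitution).
#' @keywords internal
ng86_tables <- function() {
  if (!is.null(.ng86$tables)) return(.ng86$tables)
  gc <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  nc <- length(codons)

  sites <- stats::setNames(numeric(nc), codons)
  nbrs <- stats::setNames(vector("list", nc), codons)
  for (cod in codons) {
    spl <- strsplit(cod, "")[[1]]
    s <- 0
    nb <- character(0)
    for (pos in 1:3) {
      syn <- 0L
      tot <- 0L
      for (b in .dna_bases[.dna_bases != spl[pos]]) {
        mut <- spl
        mut[pos] <- b
        mc <- paste(mut, collapse = "")
        if (gc[[mc]] == "*") next
        tot <- tot + 1L
        if (gc[[mc]] == gc[[cod]]) {
          syn <- syn + 1L
          nb <- c(nb, mc)
        }
      }
      if (tot > 0L) s <- s + syn / tot
    }
    sites[[cod]] <- s
    nbrs[[cod]] <- nb
  }

  sd_mat <- matrix(0, nc, nc, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      if (i == j) next
      pc <- .path_counts(codons[i], codons[j], gc)
      sd_mat[i, j] <- sd_mat[j, i] <- pc[1]
      nd_mat[i, j] <- nd_mat[j, i] <- pc[2]
    }
  }

  .ng86$tables <- list(codons = codons, sites = sites,
                       sd = sd_mat, nd = nd_mat, syn_neighbours = nbrs)
  .ng86$tables
}

# Split a coding sequence into codons; accepts character or XString.
codon_split <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  n <- nchar(x)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3, got ", n)
  }
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Jukes-Cantor multiple-hit correction; NA at/after saturation (p >= 3/4).
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Synonymous and nonsynonymous divergence of one codon-aligned pair (NG86)
#'
#' Counts synonymous (S) and nonsynonymous (N) sites by enumerating all
#' single-nucleotide changes per codon under the standard genetic code
#' (changes to stop codons excluded, positions renormalised so that
#' S + N = 3 x codons used), averages site counts across the two sequences,
#' counts differences by averaging over stop-free minimal mutational
#' pathways, and applies the Jukes-Cantor correction
#' d = -(3/4) log(1 - 4p/3). Codon pairs containing gaps, ambiguity codes,
#' or stop codons are masked out.
#'
#' @param seq_a,seq_b In-frame, equal-length coding sequences (character or
#'   [Biostrings::DNAString]); the alignment must be codon-aware.
#' @param min_codons Pairs with fewer valid codons are flagged `low_codons`.
#' @return Object of class `ks_estimate`: list with `ks`, `ka`, `S`, `N`,
#'   `Sd`, `Nd`, `ps`, `pn`, `codons_used`, and logical flags `saturated`
#'   (p_s >= 3/4, `ks` is `NA`) and `low_codons`.
#' @examples
#' a <- "ATGGCTGCA"
#' ks_ng86(a, a)$ks  # 0
#' @export
ks_ng86 <- function(seq_a, seq_b, min_codons = 30L) {
  tabs <- ng86_tables()
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  if (length(ca) != length(cb)) {
    stop("sequences differ in length (", length(ca), " vs ", length(cb),
         " codons)")
  }
  ok <- ca %in% tabs$codons & cb %in% tabs$codons
  if (!any(ok)) stop("no valid (sense, unambiguous) codon pairs")
  ca <- ca[ok]
  cb <- cb[ok]
  nc <- length(ca)

  S <- sum((tabs$sites[ca] + tabs$sites[cb]) / 2)
  N <- 3 * nc - S
  idx <- cbind(match(ca, tabs$codons), match(cb, tabs$codons))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0

  structure(list(
    ks = jc_correct(ps),
    ka = jc_correct(pn),
    S = S, N = N, Sd = Sd, Nd = Nd,
    ps = ps, pn = pn,
    codons_used = nc,
    saturated = ps >= 0.75,
    low_codons = nc < min_codons
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat("NG86 divergence estimate\n")
  cat(sprintf("  Ks = %s  Ka = %s\n",
              format(x$ks, digits = 4), format(x$ka, digits = 4)))
  cat(sprintf("  S = %.2f  N = %.2f  codons used = %d\n",
              x$S, x$N, x$codons_used))
  if (x$saturated) cat("  [saturated: p_s >= 3/4, Ks undefined]\n")
  if (x$low_codons) cat("  [low_codons]\n")
  invisible(x)
}

#' Per-pair Ks/Ka table for a set of codon-aligned pairs
#'
#' @param pairs A list of pairs, each a list with elements `id`, `seq_a`,
#'   `seq_b` (as produced by [simulate_divergent_pairs()]), or the full
#'   object returned by that generator.
#' @param min_codons Passed to [ks_ng86()].
#' @return `data.frame` with columns `pair_id`, `ks`, `ka`, `S`, `N`,
#'   `codons_used`, `saturated`, `low_codons`.
#' @export
ks_table <- function(pairs, min_codons = 30L) {
  if (is.list(pairs) && !is.null(pairs$pairs)) pairs <- pairs$pairs
  rows <- lapply(pairs, function(p) {
    e <- ks_ng86(p$seq_a, p$seq_b, min_codons = min_codons)
    data.frame(pair_id = p$id, ks = e$ks, ka = e$ka, S = e$S, N = e$N,
               codons_used = e$codons_used, saturated = e$saturated,
               low_codons = e$low_codons, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict Ks estimates to an interpretable range
#'
#' Keeps estimates with `lo <= Ks <= hi` (inclusive); saturated or undefined
#' (`NA`) values are always excluded. The default window \[0.01, 2.0\]
#' excludes residual allelic variation at the low end and saturation noise
#' at the high end.
#'
#' @param ks Numeric vector of Ks values, or a data.frame with a `ks` column
#'   (e.g. from [ks_table()]).
#' @param lo,hi Inclusive bounds; `lo` must not exceed `hi`.
#' @return Filtered object of the same type, with attribute `retention`
#'   (named counts: input, kept, dropped).
#' @examples
#' filter_ks(c(0.005, 0.01, 1.9, 2.0, 2.1))  # 0.01 1.9 2.0
#' @export
filter_ks <- function(ks, lo = 0.01, hi = 2.0) {
  if (lo > hi) stop("lo (", lo, ") must not exceed hi (", hi, ")")
  vals <- if (is.data.frame(ks)) ks$ks else ks
  if (is.null(vals)) stop("'ks' must be numeric or have a 'ks' column")
  keep <- !is.na(vals) & vals >= lo & vals <= hi
  out <- if (is.data.frame(ks)) ks[keep, , drop = FALSE] else ks[keep]
  if (!any(keep)) warning("no Ks values retained in [", lo, ", ", hi, "]")
  attr(out, "retention") <- c(input = length(vals), kept = sum(keep),
                              dropped = sum(!keep))
  out
}
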