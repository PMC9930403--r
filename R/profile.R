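# Assembly summary statistics, oligonucleotide observed/expected
# composition, and a simplified k-mer genome-size/heterozygosity profiler.

as_scaffold_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq_%d", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  if (is.list(x) && !is.null(x$scaffolds)) return(as_scaffold_set(x$scaffolds))
  stop("cannot interpret input as a scaffold set")
}

#' Assembly summary statistics
#'
#' N50 is the length of the scaffold at which the length-sorted cumulative
#' sum first reaches half the total assembly length (N90 analogous at 90%).
#' GC is computed over non-N bases.
#'
#' @param scaffolds A [Biostrings::DNAStringSet], named character vector,
#'   or a list with a `scaffolds` element (e.g. from [simulate_genome()]).
#' @param top_k Report the cumulative fraction of the assembly held by the
#'   `top_k` largest scaffolds.
#' @return Object of class `assembly_stats`: `n_scaffolds`, `total_length`,
#'   `n50`, `n90`, `gc_percent`, `n_percent`, `top_k`, `top_k_fraction`,
#'   and `cumulative` (scaffold id, length, cumulative length/fraction,
#'   sorted by decreasing length).
#' @examples
#' assembly_stats(c(s1 = "GGCCAT", s2 = "ATAT"))
#' @export
assembly_stats <- function(scaffolds, top_k = 10L) {
  ss <- as_scaffold_set(scaffolds)
  if (length(ss) == 0L) stop("empty scaffold set")
  if (anyDuplicated(names(ss))) stop("scaffold ids must be unique")
  lens <- Biostrings::width(ss)
  if (any(lens == 0L)) stop("scaffold sequences must be non-empty")
  total <- sum(as.double(lens))

  ord <- order(lens, decreasing = TRUE)
  cl <- cumsum(as.double(lens[ord]))
  n50 <- lens[ord][which(cl >= 0.5 * total)[1L]]
  n90 <- lens[ord][which(cl >= 0.9 * total)[1L]]

  freq <- colSums(Biostrings::alphabetFrequency(ss, baseOnly = TRUE))
  acgt <- sum(freq[c("A", "C", "G", "T")])
  gc <- 100 * sum(freq[c("G", "C")]) / acgt
  n_pct <- 100 * (total - acgt) / total

  k <- min(top_k, length(ss))
  structure(list(
    n_scaffolds = length(ss), total_length = total,
    n50 = n50, n90 = n90,
    gc_percent = gc, n_percent = n_pct,
    top_k = k, top_k_fraction = cl[k] / total,
    cumulative = data.frame(scaffold = names(ss)[ord],
                            length = lens[ord],
                            cumulative = cl,
                            cumulative_fraction = cl / total,
                            stringsAsFactors = FALSE)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly summary\n")
  cat(sprintf("  scaffolds: %d  total: %s bp\n", x$n_scaffolds,
              format(x$total_length, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  N50: %s  N90: %s\n",
              format(x$n50, big.mark = ","), format(x$n90, big.mark = ",")))
  cat(sprintf("  GC: %.2f%%  N: %.3f%%\n", x$gc_percent, x$n_percent))
  cat(sprintf("  largest %d scaffolds hold %.1f%% of the assembly\n",
              x$top_k, 100 * x$top_k_fraction))
  invisible(x)
}

.tri_classes <- function() {
  h <- c("A", "C", "T")
  list(
    CHG = paste0("C", h, "G"),
    CHH = as.vector(outer(h, h, function(a, b) paste0("C", a, b))),
    CG_containing = {
      b <- c("A", "C", "G", "T")
      unique(c(paste0("CG", b), paste0(b, "CG")))
    }
  )
}

#' Observed vs expected oligonucleotide composition
#'
#' Counts overlapping di- and trinucleotide windows on the given strand
#' (windows containing N are skipped; windows never straddle scaffold
#' boundaries) and compares them with expectations from a zero-order
#' (mononucleotide product) model: `expected(w) = W * prod(p_base)` with `W`
#' the number of valid windows. Trinucleotides are additionally aggregated
#' into the methylation-relevant classes CHG and CHH (H = A, C or T) and
#' the CG-containing words, where plant genomes typically show CG depletion
#' and CHH enrichment.
#'
#' @param scaffolds As for [assembly_stats()].
#' @return Object of class `oligo_report`: `mono` (base fractions over
#'   non-N bases), `dinuc` and `trinuc` (`data.frame`s with `word`,
#'   `observed`, `expected`, `ratio`), `classes` (CHG/CHH/CG-containing
#'   aggregates).
#' @examples
#' oligo_composition(c(s = "CACACACACA"))$dinuc
#' @export
oligo_composition <- function(scaffolds) {
  ss <- as_scaffold_set(scaffolds)
  freq <- colSums(Biostrings::alphabetFrequency(ss, baseOnly = TRUE))
  acgt <- freq[c("A", "C", "G", "T")]
  if (sum(acgt) < 3) stop("need at least 3 non-N bases")
  p <- acgt / sum(acgt)

  count_words <- function(width) {
    m <- Biostrings::oligonucleotideFrequency(ss, width = width)
    if (is.null(dim(m))) m else colSums(m)
  }
  report <- function(obs) {
    W <- sum(obs)
    words <- names(obs)
    expected <- W * vapply(strsplit(words, ""), function(b) prod(p[b]),
                           numeric(1))
    # impossible words (a constituent base absent) get ratio 0 when also
    # unobserved, Inf if somehow observed
    data.frame(word = words, observed = as.numeric(obs),
               expected = expected,
               ratio = ifelse(expected > 0, obs / expected,
                              ifelse(obs == 0, 0, Inf)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  dinuc <- report(count_words(2L))
  trinuc <- report(count_words(3L))

  classes <- do.call(rbind, lapply(names(.tri_classes()), function(cl) {
    w <- .tri_classes()[[cl]]
    sub <- trinuc[trinuc$word %in% w, ]
    data.frame(class = cl, observed = sum(sub$observed),
               expected = sum(sub$expected),
               ratio = sum(sub$observed) / sum(sub$expected),
               stringsAsFactors = FALSE)
  }))

  structure(list(mono = p, dinuc = dinuc, trinuc = trinuc,
                 classes = classes),
            class = "oligo_report")
}

#' @export
print.oligo_report <- function(x, ...) {
  cat("Oligonucleotide composition (observed/expected, zero-order model)\n")
  cat("  base fractions:",
      paste(sprintf("%s=%.3f", names(x$mono), x$mono), collapse = " "), "\n")
  cg <- x$dinuc[x$dinuc$word == "CG", ]
  cat(sprintf("  CG dinucleotide ratio: %.3f\n", cg$ratio))
  print(x$classes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Genome size and heterozygosity from a k-mer histogram
#'
#' A simplified diploid k-mer profiler. The histogram is smoothed with a
#' 3-bin moving average; bins up to the first local minimum (the trough
#' under the read-error spike) are the error region. Among local maxima
#' beyond the trough whose smoothed count is at least 5% of the largest
#' maximum, the deepest is taken as the homozygous peak and a maximum near
#' half its depth (if any) as the heterozygous peak. When only a single
#' peak exists but a substantial share (>10%) of the k-mer mass lies beyond
#' 1.5x its depth — the signature of a homozygous shoulder buried in the
#' heterozygous peak's tail at high heterozygosity — that peak is read as
#' the heterozygous one and the homozygous depth is taken as twice it.
#' Then:
#' \itemize{
#'   \item genome size = sum(depth x count) over non-error bins, divided by
#'     the homozygous peak depth;
#'   \item heterozygosity: with `m` the fraction of non-error k-mer mass on
#'     the heterozygous side of the midpoint between the two peaks,
#'     `h = 1 - (1 - m)^(1/k)` (the exact inversion of the probability
#'     `m = 1 - (1 - h)^k` that a k-mer overlaps a heterozygous site;
#'     `m/k` to first order);
#'   \item error rate: same inversion applied to the error-region mass
#'     fraction.
#' }
#'
#' @param hist A `kmer_histogram` (from [simulate_kmer_histogram()] or
#'   [read_kmer_histogram()]) or a `data.frame` with `depth` and `count`.
#' @param k K-mer length; taken from the histogram object when present.
#' @return Object of class `kmer_profile`: `genome_size_bp`,
#'   `heterozygosity`, `error_rate`, `hom_peak_depth`/`het_peak_depth`
#'   (mass-centroid refined, so non-integer; het `NA` when absent),
#'   `hom_peak_bin`/`het_peak_bin` (detected histogram bins),
#'   `het_peak_found`, `trough_depth`.
#' @examples
#' h <- simulate_kmer_histogram(seed = 1, genome_size = 2e5,
#'                              heterozygosity = 0, error_rate = 0)
#' kmer_profile(h)$genome_size_bp
#' @export
kmer_profile <- function(hist, k = NULL) {
  if (is.data.frame(hist)) {
    bins <- hist
    if (is.null(k)) stop("supply k when profiling a bare histogram table")
  } else {
    bins <- hist$bins
    if (is.null(k)) k <- hist$k
  }
  if (is.null(k) || is.na(k)) stop("k-mer length unknown")
  stopifnot(all(bins$depth >= 1), all(diff(bins$depth) > 0),
            all(bins$count >= 0))

  max_d <- max(bins$depth)
  if (max_d < 3L) {
    stop("no k-mer coverage peak found above the error trough; ",
         "refusing to report a genome size")
  }
  full <- numeric(max_d)
  full[bins$depth] <- bins$count
  sm <- stats::filter(full, rep(1 / 3, 3), sides = 2)
  sm[1L] <- mean(full[1:2])
  sm[max_d] <- mean(full[(max_d - 1L):max_d])
  sm <- as.numeric(sm)

  is_min <- function(i) sm[i] <= sm[i - 1L] && sm[i] < sm[i + 1L]
  # plateau ties resolve toward the higher depth
  is_max <- function(i) sm[i] >= sm[i - 1L] && sm[i] > sm[i + 1L]
  interior <- if (max_d >= 3L) 2:(max_d - 1L) else integer(0)
  minima <- interior[vapply(interior, is_min, logical(1))]
  maxima <- interior[vapply(interior, is_max, logical(1))]
  # a rising start means no error spike: no error region
  trough <- if (length(minima) && (length(maxima) == 0L ||
                                   minima[1L] < max(maxima))) minima[1L] else 0L
  cand <- maxima[maxima > trough]
  if (length(cand) == 0L && max_d >= 2L && sm[max_d] > sm[max_d - 1L]) {
    cand <- max_d
  }
  if (length(cand) == 0L) {
    stop("no k-mer coverage peak found above the error trough; ",
         "refusing to report a genome size")
  }
  cand <- cand[sm[cand] >= 0.05 * max(sm[cand])]

  nonerr <- bins$depth > trough
  mass <- as.double(bins$depth) * as.double(bins$count)
  total_mass <- sum(mass[nonerr])

  hom <- max(cand)
  het <- NA_integer_
  lower <- cand[cand < hom]
  half <- lower[hom / lower >= 1.6 & hom / lower <= 2.4]
  if (length(half)) {
    # classic two-peak histogram: deepest peak homozygous, its half-depth
    # companion heterozygous
    het <- half[which.max(sm[half])]
  } else if (length(cand) == 1L) {
    # one peak only: under strong heterozygosity the homozygous component
    # is a shoulder, not a maximum, and the single peak sits at half
    # coverage. Decide from the k-mer mass beyond 1.5x the peak, which is
    # negligible for a lone homozygous (Poisson) peak.
    f_above <- sum(mass[nonerr & bins$depth > 1.5 * hom]) / total_mass
    if (f_above > 0.10) {
      het <- hom
      hom <- 2L * hom
    }
  } else if (length(lower)) {
    het <- lower[which.max(sm[lower])]
  }

  # de-quantize peak depths: 3-point parabolic apex interpolation around
  # the detected bin (offset clamped to one bin)
  # the +0.5 corrects the half-bin gap between the apex of a discrete
  # Poisson-spread peak (~ lambda - 1/2) and its mean depth lambda
  interp_peak <- function(d) {
    if (d <= 1L || d >= max_d) return(as.numeric(d) + 0.5)
    den <- sm[d - 1L] - 2 * sm[d] + sm[d + 1L]
    off <- if (den < 0) 0.5 * (sm[d - 1L] - sm[d + 1L]) / den else 0
    d + max(-1, min(1, off)) + 0.5
  }
  het_ref <- if (!is.na(het)) interp_peak(het) else NA_real_
  # each peak's apex is dragged toward the other by the other's tail, so
  # trust the dominant (higher-count) peak and derive the other through
  # the 2:1 depth relation between homozygous and heterozygous coverage;
  # this also covers the buried-shoulder case where the homozygous
  # component is not a local maximum at all
  hom_ref <- if (!is.na(het) && (!(hom %in% cand) || sm[het] > sm[hom])) {
    2 * het_ref
  } else {
    interp_peak(hom)
  }
  if (!is.na(het) && hom %in% cand && sm[het] <= sm[hom]) {
    het_ref <- hom_ref / 2
  }
  genome_size <- total_mass / hom_ref

  invert <- function(m) 1 - (1 - m)^(1 / k)
  heterozygosity <- 0
  if (!is.na(het)) {
    boundary <- (het_ref + hom_ref) / 2
    m_het <- sum(mass[nonerr & bins$depth <= boundary]) / total_mass
    heterozygosity <- invert(m_het)
  }
  err_mass <- sum(mass[!nonerr])
  error_rate <- invert(err_mass / (err_mass + total_mass))

  structure(list(genome_size_bp = genome_size,
                 heterozygosity = heterozygosity,
                 error_rate = error_rate,
                 hom_peak_depth = hom_ref,
                 het_peak_depth = het_ref,
                 hom_peak_bin = as.integer(hom),
                 het_peak_bin = as.integer(het),
                 het_peak_found = !is.na(het),
                 trough_depth = trough,
                 k = as.integer(k)),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("k-mer profile (simplified diploid model, k =", x$k, ")\n")
  cat(sprintf("  genome size: %s bp\n",
              format(round(x$genome_size_bp), big.mark = ",",
                     scientific = FALSE)))
  cat(sprintf("  heterozygosity: %.2f%%  read error rate: %.2f%%\n",
              100 * x$heterozygosity, 100 * x$error_rate))
  cat(sprintf("  peaks: hom depth %.1f%s\n", x$hom_peak_depth,
              if (x$het_peak_found)
                sprintf(", het depth %.1f", x$het_peak_depth)
              else " (no heterozygous peak)"))
  invisible(x)
}
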