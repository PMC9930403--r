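# Diploid k-mer depth histograms: an error spike at depth ~1, a
# heterozygous peak near half coverage, and a homozygous peak near full
# coverage, with Poisson spread.

#' Simulate a diploid k-mer depth histogram
#'
#' A haploid genome of `genome_size` k-mer loci is split into heterozygous
#' loci (a k-mer overlaps at least one heterozygous site; probability
#' `1 - (1 - heterozygosity)^k`) and homozygous loci. Homozygous loci
#' contribute one k-mer at Poisson depth around the effective coverage
#' `coverage * (1 - error_rate)^k` (the share of error-free copies);
#' heterozygous loci contribute two distinct k-mers at half that depth.
#' Sequencing errors add a spike of depth-1 k-mers whose total mass makes
#' the full histogram mass consistent with `genome_size * coverage`.
#'
#' @param seed Global seed (fixed-offset child stream).
#' @param genome_size Haploid genome size in bp (= k-mer loci).
#' @param heterozygosity Per-base heterozygosity fraction in \[0, 1\].
#' @param coverage Mean k-mer coverage depth of homozygous loci before
#'   error loss.
#' @param error_rate Per-base read error rate in \[0, 1\].
#' @param k K-mer length.
#' @return List of class `kmer_histogram`: `k`, `bins` (`data.frame` with
#'   strictly increasing `depth` and `count`), and `truth` (the generating
#'   parameters).
#' @examples
#' h <- simulate_kmer_histogram(seed = 1, genome_size = 2e5,
#'                              heterozygosity = 0, error_rate = 0)
#' head(h$bins)
#' @export
simulate_kmer_histogram <- function(seed, genome_size = 1e6,
                                    heterozygosity = 0.05, coverage = 30,
                                    error_rate = 0.0048, k = 21L) {
  stopifnot(genome_size > 0, coverage > 0, k >= 1L,
            heterozygosity >= 0, heterozygosity <= 1,
            error_rate >= 0, error_rate <= 1)
  set.seed(child_seed(seed, "kmer"))
  G <- round(genome_size)
  het_kmer_frac <- 1 - (1 - heterozygosity)^k
  n_het <- round(G * het_kmer_frac)
  n_hom <- G - n_het
  c_eff <- coverage * (1 - error_rate)^k

  depths <- c(stats::rpois(n_hom, c_eff), stats::rpois(2L * n_het, c_eff / 2))
  depths <- depths[depths > 0L]
  tab <- tabulate(depths)
  # error k-mers: one token per sequenced k-mer containing >=1 error
  err_frac <- 1 - (1 - error_rate)^k
  n_err <- stats::rpois(1L, G * coverage * err_frac)
  if (n_err > 0L) tab[1L] <- tab[1L] + n_err

  keep <- which(tab > 0L)
  structure(list(k = as.integer(k),
                 bins = data.frame(depth = keep, count = tab[keep]),
                 truth = list(genome_size = G,
                              heterozygosity = heterozygosity,
                              coverage = coverage, error_rate = error_rate,
                              het_kmer_fraction = het_kmer_frac,
                              effective_coverage = c_eff)),
            class = "kmer_histogram")
}

#' Write a k-mer histogram as a two-column text file
#'
#' @param hist A `kmer_histogram` or a `data.frame` with `depth`, `count`.
#' @param path Output file (whitespace-delimited depth/count, no header).
#' @export
write_kmer_histogram <- function(hist, path) {
  bins <- if (is.data.frame(hist)) hist else hist$bins
  utils::write.table(bins, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column k-mer histogram file
#'
#' @param path Whitespace-delimited depth/count file (jellyfish/KMC style).
#' @param k K-mer length the histogram was computed at (not stored in the
#'   two-column format; needed for heterozygosity estimation).
#' @return List of class `kmer_histogram` with `k` and `bins`.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  df <- utils::read.table(path, col.names = c("depth", "count"))
  if (any(diff(df$depth) <= 0)) df <- df[order(df$depth), ]
  structure(list(k = as.integer(k), bins = df), class = "kmer_histogram")
}
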