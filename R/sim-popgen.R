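# Bi-parental mapping population with a planted sex-linked marker subset:
# genotype codes {A, H, B} (missing as NA), offspring sex labels, and marker
# positions on named scaffolds.

#' Simulate a bi-parental mapping population with sex-linked markers
#'
#' Test-cross markers segregate ~1:1 (A:H) and F2-type markers ~1:2:1
#' (A:H:B) among offspring. A `sex_linked_fraction` of markers is placed on
#' one designated scaffold and made to predict sex exactly (males `H`,
#' females `A`), apart from an optional per-call `genotype_error` flip.
#' Remaining markers are spread over the other scaffolds and segregate
#' independently of sex.
#'
#' @param seed Global seed (fixed-offset child stream).
#' @param n_offspring Offspring count (parents are not emitted).
#' @param n_markers Total marker count.
#' @param sex_linked_fraction Fraction of markers that are sex-linked.
#' @param n_scaffolds Number of named scaffolds.
#' @param sex_scaffold Scaffold carrying the sex-linked subset.
#' @param f2_fraction Fraction of non-sex-linked markers with F2-type
#'   (1:2:1) segregation; the rest are test-cross (1:1).
#' @param genotype_error Per-call probability that a sex-linked genotype is
#'   flipped.
#' @param missing_rate Per-call missing-data probability.
#' @return List of class `mapping_population`: `genotypes` (markers x
#'   offspring character matrix of `"A"/"H"/"B"`/`NA`), `sex` (factor
#'   `female`/`male` per offspring), `markers` (`data.frame`: `marker_id`,
#'   `scaffold`, `pos_bp`, `type`, `sex_linked`).
#' @examples
#' pop <- simulate_mapping_population(seed = 1, n_markers = 50)
#' table(pop$sex)
#' @export
simulate_mapping_population <- function(seed, n_offspring = 281L,
                                        n_markers = 2000L,
                                        sex_linked_fraction = 0.05,
                                        n_scaffolds = 10L,
                                        sex_scaffold = "Scaffold_3",
                                        f2_fraction = 0.3,
                                        genotype_error = 0,
                                        missing_rate = 0) {
  stopifnot(n_offspring >= 2L, n_markers >= 1L,
            sex_linked_fraction >= 0, sex_linked_fraction <= 1,
            f2_fraction >= 0, f2_fraction <= 1,
            genotype_error >= 0, genotype_error <= 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(child_seed(seed, "popgen"))

  sex <- factor(ifelse(stats::rbinom(n_offspring, 1L, 0.5) == 1L,
                       "male", "female"),
                levels = c("female", "male"))
  scafs <- sprintf("Scaffold_%d", seq_len(n_scaffolds))
  if (!sex_scaffold %in% scafs) scafs[1L] <- sex_scaffold

  n_sex <- round(n_markers * sex_linked_fraction)
  sex_linked <- seq_len(n_markers) <= n_sex
  scaffold <- character(n_markers)
  scaffold[sex_linked] <- sex_scaffold
  other <- setdiff(scafs, sex_scaffold)
  if (length(other) == 0L) other <- sex_scaffold
  scaffold[!sex_linked] <- sample(other, n_markers - n_sex, replace = TRUE)

  type <- character(n_markers)
  type[sex_linked] <- "sex_linked"
  type[!sex_linked] <- ifelse(
    stats::runif(n_markers - n_sex) < f2_fraction, "f2", "testcross")

  geno <- matrix(NA_character_, n_markers, n_offspring)
  male <- sex == "male"
  for (m in seq_len(n_markers)) {
    g <- switch(type[m],
      sex_linked = ifelse(male, "H", "A"),
      testcross = sample(c("A", "H"), n_offspring, replace = TRUE),
      f2 = sample(c("A", "H", "B"), n_offspring, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25)))
    if (type[m] == "sex_linked" && genotype_error > 0) {
      flip <- stats::runif(n_offspring) < genotype_error
      g[flip] <- ifelse(g[flip] == "H", "A", "H")
    }
    geno[m, ] <- g
  }
  if (missing_rate > 0) {
    geno[matrix(stats::runif(length(geno)) < missing_rate,
                nrow(geno))] <- NA_character_
  }
  marker_id <- sprintf("mk_%05d", seq_len(n_markers))
  rownames(geno) <- marker_id
  colnames(geno) <- sprintf("off_%03d", seq_len(n_offspring))

  markers <- data.frame(marker_id = marker_id, scaffold = scaffold,
                        pos_bp = sample.int(3e6, n_markers, replace = TRUE),
                        type = type, sex_linked = sex_linked,
                        stringsAsFactors = FALSE)
  structure(list(genotypes = geno, sex = sex, markers = markers),
            class = "mapping_population")
}

#' Write a genotype matrix as TSV (markers as rows)
#'
#' Codes `A`/`H`/`B`, missing as `-`; first column `marker`.
#'
#' @param pop A `mapping_population` (or a character matrix).
#' @param path Output TSV.
#' @export
write_genotypes <- function(pop, path) {
  geno <- if (is.matrix(pop)) pop else pop$genotypes
  out <- ifelse(is.na(geno), "-", geno)
  df <- data.frame(marker = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype TSV written by [write_genotypes()]
#'
#' @param path Input TSV.
#' @return Character matrix (markers x individuals), `-` mapped to `NA`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m[m == "-"] <- NA_character_
  m
}
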