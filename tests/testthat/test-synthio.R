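# Synthetic-data generators: determinism, placement constraints, and
# distributional fidelity at fixed seeds.

test_that("simulate_genome places non-overlapping genes and is reproducible", {
  g <- simulate_genome(seed = 1, scaffold_length = 10000L, n_genes = 10L)
  expect_equal(length(unique(g$genes$gene_id)), 10L)
  expect_no_error(synteks:::validate_gene_models(g$genes))
  # whole-gene spans must not overlap either
  spans <- do.call(rbind, lapply(split(g$genes, g$genes$gene_id), function(x)
    data.frame(start = min(x$start), end = max(x$end))))
  spans <- spans[order(spans$start), ]
  expect_true(all(spans$start[-1L] > spans$end[-nrow(spans)]))
  expect_true(all(g$genes$end <= 10000L))

  d1 <- file.path(tempdir(), "gen1")
  d2 <- file.path(tempdir(), "gen2")
  simulate_genome(seed = 7, n_genes = 5L, out_dir = d1)
  simulate_genome(seed = 7, n_genes = 5L, out_dir = d2)
  for (f in c("genome.fa", "genes.gff3")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("simulate_genome rejects genomes too small for the genes", {
  expect_error(simulate_genome(seed = 1, scaffold_length = 1000L,
                               n_genes = 10L),
               "too small")
})

test_that("uniform composition is recovered at the megabase scale", {
  g <- simulate_genome(seed = 3, scaffold_length = 1000000L, n_genes = 0L)
  freq <- Biostrings::alphabetFrequency(g$scaffolds[[1]], baseOnly = TRUE)
  p <- freq[c("A", "C", "G", "T")] / 1e6
  # binomial sd at n = 1e6 is ~4.3e-4; 0.01 is a >20-sigma band
  expect_true(all(abs(p - 0.25) < 0.01))
})

test_that("divergent pairs: zero-divergence component gives identical pairs", {
  dp <- simulate_divergent_pairs(
    seed = 1, n_pairs = 5L,
    ks_components = data.frame(mean_ks = 0, sd_log = 0, weight = 1),
    codon_length = 60L)
  for (p in dp$pairs) expect_identical(p$seq_a, p$seq_b)
  expect_true(all(dp$truth$ks_realized == 0))
})

test_that("divergent pairs are reproducible and in-frame without stops", {
  dp1 <- simulate_divergent_pairs(seed = 5, n_pairs = 10L, codon_length = 60L)
  dp2 <- simulate_divergent_pairs(seed = 5, n_pairs = 10L, codon_length = 60L)
  expect_identical(dp1, dp2)
  stops <- c("TAA", "TAG", "TGA")
  for (p in dp1$pairs) {
    expect_equal(nchar(p$seq_a), nchar(p$seq_b))
    expect_equal(nchar(p$seq_a) %% 3L, 0L)
    cods <- substring(p$seq_b, seq(1, nchar(p$seq_b), 3),
                      seq(3, nchar(p$seq_b), 3))
    expect_false(any(cods %in% stops))
  }
})

test_that("divergent pairs reject components beyond the saturation bound", {
  expect_error(simulate_divergent_pairs(
    seed = 1, n_pairs = 2L,
    ks_components = data.frame(mean_ks = 5, sd_log = 0, weight = 1)),
    "saturation")
})

test_that("synteny dataset: independent labels match the binomial oracle", {
  sim <- simulate_synteny_dataset(seed = 11, n_blocks = 400L,
                                  anchors_per_block = 5L,
                                  p_terpene = 0.5, p_defense = 0.5,
                                  dependence = 0, noise_rate = 0,
                                  block_spacer_genes = 5L)
  both <- sum(sim$truth$terpene & sim$truth$defense)
  expected <- 400 * 0.5 * 0.5
  sd3 <- 3 * sqrt(400 * 0.25 * 0.75)
  expect_lt(abs(both - expected), sd3)
})

test_that("synteny dataset: ltr_rate = 0 gives no repeat intervals", {
  sim <- simulate_synteny_dataset(seed = 2, n_blocks = 10L, ltr_rate = 0)
  expect_equal(nrow(sim$repeats), 0L)
})

test_that("synteny dataset is reproducible for a fixed seed", {
  s1 <- simulate_synteny_dataset(seed = 4, n_blocks = 8L)
  s2 <- simulate_synteny_dataset(seed = 4, n_blocks = 8L)
  expect_identical(s1, s2)
})

test_that("kmer histogram: haploid error-free case has one peak at coverage", {
  h <- simulate_kmer_histogram(seed = 1, genome_size = 2e5,
                               heterozygosity = 0, coverage = 30,
                               error_rate = 0)
  peak <- h$bins$depth[which.max(h$bins$count)]
  expect_lt(abs(peak - 30), 2)
  # total k-mer mass consistent with genome_size x coverage
  mass <- sum(as.double(h$bins$depth) * h$bins$count)
  expect_lt(abs(mass / (2e5 * 30) - 1), 0.01)
})

test_that("kmer histogram: het-peak mass grows with heterozygosity", {
  mass_below_half <- function(hh) {
    h <- simulate_kmer_histogram(seed = 6, genome_size = 2e5,
                                 heterozygosity = hh, coverage = 30,
                                 error_rate = 0)
    b <- h$bins
    sum(b$count[b$depth > 4 & b$depth <= 20]) / sum(b$count[b$depth > 4])
  }
  expect_gt(mass_below_half(0.05), mass_below_half(0.01))
})

test_that("kmer histogram is reproducible for a fixed seed", {
  expect_identical(simulate_kmer_histogram(seed = 3, genome_size = 1e5),
                   simulate_kmer_histogram(seed = 3, genome_size = 1e5))
})

test_that("mapping population: segregation ratios and determinism", {
  pop <- simulate_mapping_population(seed = 8, n_offspring = 281L,
                                     n_markers = 400L,
                                     sex_linked_fraction = 0.05)
  expect_identical(pop, simulate_mapping_population(
    seed = 8, n_offspring = 281L, n_markers = 400L,
    sex_linked_fraction = 0.05))
  tc <- pop$genotypes[pop$markers$type == "testcross", , drop = FALSE]
  frac_a <- mean(tc == "A")
  expect_lt(abs(frac_a - 0.5), 0.02)
  f2 <- pop$genotypes[pop$markers$type == "f2", , drop = FALSE]
  expect_lt(abs(mean(f2 == "H") - 0.5), 0.02)
  expect_lt(abs(mean(f2 == "A") - 0.25), 0.02)
  # sex-linked markers predict sex exactly at zero error
  sl <- pop$genotypes[pop$markers$sex_linked, , drop = FALSE]
  expect_true(all(sl[, pop$sex == "male"] == "H"))
  expect_true(all(sl[, pop$sex == "female"] == "A"))
})

test_that("a single fully sex-linked marker reaches chi-squared p < 1e-10", {
  pop <- simulate_mapping_population(seed = 9, n_offspring = 281L,
                                     n_markers = 20L,
                                     sex_linked_fraction = 1 / 20)
  scan <- sex_association_scan(pop)
  p_sl <- scan$table$p[pop$markers$sex_linked]
  expect_lt(max(p_sl), 1e-10)
  # closed form: perfect 2x2 association gives X^2 = n
  n_eff <- sum(!is.na(pop$genotypes[1, ]))
  expect_equal(scan$table$statistic[1], n_eff, tolerance = 1e-8)
})

test_that("genotype TSV round-trips", {
  pop <- simulate_mapping_population(seed = 2, n_offspring = 20L,
                                     n_markers = 15L, missing_rate = 0.1)
  f <- tempfile(fileext = ".tsv")
  write_genotypes(pop, f)
  expect_identical(read_genotypes(f), pop$genotypes)
})
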