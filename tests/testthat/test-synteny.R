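# Collinearity parsing, DP block detection vs exhaustive search, and block
# content statistics.

test_that("parse_collinearity handles empty and malformed files", {
  f <- tempfile()
  writeLines(c("############### Parameters ###############",
               "# MATCH_SCORE: 50"), f)
  expect_length(parse_collinearity(f), 0L)

  writeLines(c("## Alignment 0: score=100 e_value=1e-10 N=10 s1&s2 plus",
               sprintf("0-%d: geneA%d geneB%d 1e-5", 0:8, 0:8, 0:8)), f)
  expect_error(parse_collinearity(f), "N=10.*9 anchor")
})

test_that("collinearity writer/parser round-trips synthetic blocks", {
  sim <- simulate_synteny_dataset(seed = 31, n_blocks = 50L,
                                  anchors_per_block = 8L)
  bl <- detect_blocks(sim$genes_a, sim$genes_b, sim$pairs)
  f <- tempfile(fileext = ".collinearity")
  write_collinearity(bl, f)
  back <- parse_collinearity(f)
  expect_length(back, length(bl))
  for (i in seq_along(bl)) {
    expect_equal(back[[i]]$anchors$gene_a, bl[[i]]$anchors$gene_a)
    expect_equal(back[[i]]$anchors$gene_b, bl[[i]]$anchors$gene_b)
    expect_equal(back[[i]]$orientation, bl[[i]]$orientation)
    expect_equal(back[[i]]$scaffold_a, bl[[i]]$scaffold_a)
    expect_equal(back[[i]]$scaffold_b, bl[[i]]$scaffold_b)
  }
})

test_that("a duplicated scaffold yields one full-length block", {
  genes_a <- data.frame(gene_id = sprintf("a%02d", 1:20), scaffold = "sA",
                        rank = 1:20, stringsAsFactors = FALSE)
  genes_b <- data.frame(gene_id = sprintf("b%02d", 1:20), scaffold = "sB",
                        rank = 1:20, stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = genes_a$gene_id, gene_b = genes_b$gene_id,
                      stringsAsFactors = FALSE)
  bl <- detect_blocks(genes_a, genes_b, pairs,
                      synteny_config(min_anchors = 5L))
  expect_length(bl, 1L)
  expect_equal(nrow(bl[[1]]$anchors), 20L)
  expect_equal(bl[[1]]$orientation, "same")
  # reversed order on one axis gives an inverted block
  pairs_rev <- data.frame(gene_a = genes_a$gene_id,
                          gene_b = rev(genes_b$gene_id),
                          stringsAsFactors = FALSE)
  bl2 <- detect_blocks(genes_a, genes_b, pairs_rev,
                       synteny_config(min_anchors = 5L))
  expect_length(bl2, 1L)
  expect_equal(bl2[[1]]$orientation, "inverted")
})

test_that("DP chaining equals exhaustive search on small random instances", {
  set.seed(77)
  cfg <- synteny_config(min_anchors = 2L, max_gap = 25L,
                        collapse_tandem = FALSE)
  for (r in 1:60) {
    n <- sample(5:12, 1L)
    max_gap <- sample(c(3L, 25L), 1L)
    ra <- sample.int(n)
    rb <- sample.int(n)
    dp_len <- max(length(synteks:::chain_dp(ra, rb, max_gap)),
                  length(synteks:::chain_dp(ra, -rb, max_gap)))
    expect_equal(dp_len, oracle_longest_chain(ra, rb, max_gap),
                 info = sprintf("r=%d gap=%d", r, max_gap))
  }
})

test_that("detector recovers all generated blocks at zero noise", {
  sim <- simulate_synteny_dataset(seed = 41, n_blocks = 40L,
                                  anchors_per_block = 10L, noise_rate = 0)
  bl <- detect_blocks(sim$genes_a, sim$genes_b, sim$pairs)
  # every true block recovered exactly: same anchor sets
  truth_keys <- vapply(split(sim$anchor_truth, sim$anchor_truth$block_id),
                       function(tb) paste(sort(paste(tb$gene_a, tb$gene_b)),
                                          collapse = ";"), character(1))
  det_keys <- vapply(bl, function(b)
    paste(sort(paste(b$anchors$gene_a, b$anchors$gene_b)), collapse = ";"),
    character(1))
  expect_gte(mean(truth_keys %in% det_keys), 0.95)
  expect_length(bl, 40L)
})

test_that("anchors within detected blocks are strictly monotone", {
  sim <- simulate_synteny_dataset(seed = 51, n_blocks = 20L,
                                  anchors_per_block = 8L, noise_rate = 0.5)
  bl <- detect_blocks(sim$genes_a, sim$genes_b, sim$pairs)
  for (b in bl) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    d <- diff(b$anchors$rank_b)
    if (b$orientation == "same") expect_true(all(d > 0))
    else expect_true(all(d < 0))
  }
})

test_that("block_stats: LTR coverage matches a per-base bitmap oracle", {
  sim <- simulate_synteny_dataset(seed = 61, n_blocks = 12L,
                                  anchors_per_block = 6L, ltr_rate = 0.7)
  bl <- detect_blocks(sim$genes_a, sim$genes_b, sim$pairs)
  genes <- rbind(sim$genes_a[, c("gene_id", "scaffold", "start", "end")],
                 sim$genes_b[, c("gene_id", "scaffold", "start", "end")])
  bs <- block_stats(bl, genes, repeats = sim$repeats, labels = sim$labels)
  for (i in seq_along(bl)) {
    b <- bl[[i]]
    sa <- genes[match(b$anchors$gene_a, genes$gene_id), ]
    sa <- sa[order(sa$start), ]
    gaps <- data.frame(start = sa$end[-nrow(sa)] + 1L,
                       end = sa$start[-1L] - 1L)
    gaps <- gaps[gaps$end >= gaps$start, ]
    reps <- sim$repeats[sim$repeats$scaffold == b$scaffold_a, ]
    expect_equal(bs$ltr_bases[i], oracle_interval_coverage(gaps, reps))
  }
  # zero-rate dataset: all fractions zero
  sim0 <- simulate_synteny_dataset(seed = 62, n_blocks = 5L, ltr_rate = 0)
  bl0 <- detect_blocks(sim0$genes_a, sim0$genes_b, sim0$pairs)
  genes0 <- rbind(sim0$genes_a[, c("gene_id", "scaffold", "start", "end")],
                  sim0$genes_b[, c("gene_id", "scaffold", "start", "end")])
  bs0 <- block_stats(bl0, genes0, repeats = sim0$repeats)
  expect_true(all(bs0$ltr_fraction == 0))
})

test_that("block_stats: a fully covered gap gives the exact fraction", {
  genes <- data.frame(gene_id = c("a1", "a2", "b1", "b2"),
                      scaffold = c("sA", "sA", "sB", "sB"),
                      start = c(100L, 500L, 10L, 200L),
                      end = c(199L, 599L, 99L, 299L),
                      stringsAsFactors = FALSE)
  bl <- structure(list(synteks:::new_block(
    "1", "sA", "sB", "same",
    data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
               stringsAsFactors = FALSE))), class = "synteny_blocks")
  reps <- data.frame(scaffold = "sA", start = 200L, end = 499L)
  bs <- block_stats(bl, genes, repeats = reps)
  expect_equal(bs$gap_bases, 300L)
  expect_equal(bs$ltr_fraction, 1.0)
  expect_error(block_stats(bl, genes[-1, ]), "absent")
})

test_that("scaffold_feature_counts deduplicates genes across blocks", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      scaffold = c("sA", "sA", "sB"),
                      stringsAsFactors = FALSE)
  mkb <- function(id, a, b) synteks:::new_block(
    id, "sA", "sB", "same",
    data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  bl <- structure(list(mkb("1", c("g1", "g2"), c("g3", "g3")),
                       mkb("2", "g1", "g3")), class = "synteny_blocks")
  labels <- data.frame(gene_id = "g1", label = "defense",
                       stringsAsFactors = FALSE)
  counts <- scaffold_feature_counts(bl, genes, labels, "defense")
  expect_equal(counts$count[counts$scaffold == "sA"], 1L)
  none <- scaffold_feature_counts(bl, genes, labels, "terpene")
  expect_equal(nrow(none), 0L)
})

test_that("generator label tallies match scaffold_feature_counts", {
  sim <- simulate_synteny_dataset(seed = 71, n_blocks = 30L,
                                  p_terpene = 0.5, p_defense = 0.5,
                                  noise_rate = 0)
  bl <- detect_blocks(sim$genes_a, sim$genes_b, sim$pairs)
  genes <- rbind(sim$genes_a[, c("gene_id", "scaffold")],
                 sim$genes_b[, c("gene_id", "scaffold")])
  counts <- scaffold_feature_counts(bl, genes, sim$labels, "defense")
  truth <- sim$scaffold_label_counts
  truth <- truth[truth$label == "defense" & truth$Freq > 0, ]
  for (i in seq_len(nrow(truth))) {
    expect_equal(counts$count[counts$scaffold == truth$scaffold[i]],
                 truth$Freq[i], info = truth$scaffold[i])
  }
})

test_that("tandem arrays collapse to their first member before chaining", {
  genes_a <- data.frame(gene_id = sprintf("a%02d", 1:12), scaffold = "sA",
                        rank = 1:12,
                        family = c("f1", "f1", "f1", letters[2:10]),
                        stringsAsFactors = FALSE)
  genes_b <- data.frame(gene_id = sprintf("b%02d", 1:10), scaffold = "sB",
                        rank = 1:10, family = c("f1", letters[2:10]),
                        stringsAsFactors = FALSE)
  # every member of the a-side tandem array matches b01
  pairs <- rbind(
    data.frame(gene_a = c("a01", "a02", "a03"), gene_b = "b01",
               stringsAsFactors = FALSE),
    data.frame(gene_a = sprintf("a%02d", 4:12),
               gene_b = sprintf("b%02d", 2:10), stringsAsFactors = FALSE))
  collapsed <- detect_blocks(genes_a, genes_b, pairs,
                             synteny_config(min_anchors = 5L,
                                            collapse_tandem = TRUE))
  expect_length(collapsed, 1L)
  expect_false(any(c("a02", "a03") %in% collapsed[[1]]$anchors$gene_a))
  raw <- detect_blocks(genes_a, genes_b, pairs,
                       synteny_config(min_anchors = 5L,
                                      collapse_tandem = FALSE))
  expect_length(raw, 1L)
})
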