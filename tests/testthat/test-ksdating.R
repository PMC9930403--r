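# NG86 estimation, Ks filtering, mixture fitting with ICL, primary-peak
# selection, divergence times and the molecular-clock LRT.

test_that("ks_ng86: identical sequences give Ks = Ka = 0 and S + N = 3L", {
  s <- paste(rep(c("ATG", "GCT", "AAA", "CCG", "TTC"), 12L), collapse = "")
  e <- ks_ng86(s, s)
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
  expect_equal(e$S + e$N, 3 * e$codons_used, tolerance = 1e-9)
})

test_that("ks_ng86 is symmetric and masks invalid codons", {
  dp <- simulate_divergent_pairs(seed = 3, n_pairs = 5L, codon_length = 80L)
  for (p in dp$pairs) {
    a <- ks_ng86(p$seq_a, p$seq_b)
    b <- ks_ng86(p$seq_b, p$seq_a)
    expect_equal(a$ks, b$ks)
    expect_equal(a$ka, b$ka)
  }
  with_n <- ks_ng86("ATGNNNGCT", "ATGAAAGCT")
  expect_equal(with_n$codons_used, 2L)
  expect_error(ks_ng86("NNN", "NNN"), "no valid")
  expect_error(ks_ng86("ATGC", "ATGC"), "multiple of 3")
})

test_that("single fourfold-degenerate difference matches the site oracle", {
  # GGT -> GGC: third position of glycine, fourfold degenerate, on an
  # alanine background (also fourfold, so S is large and p_s is small)
  a <- paste(c("GGT", rep("GCT", 99L)), collapse = "")
  b <- paste(c("GGC", rep("GCT", 99L)), collapse = "")
  e <- ks_ng86(a, b, min_codons = 10L)
  S_oracle <- sum(vapply(c("GGT", rep("GCT", 99L)), oracle_syn_sites,
                         numeric(1)) / 2 +
                  vapply(c("GGC", rep("GCT", 99L)), oracle_syn_sites,
                         numeric(1)) / 2)
  expect_equal(e$S, S_oracle, tolerance = 1e-9)
  expect_equal(e$ks, -0.75 * log(1 - 4 * (1 / S_oracle) / 3),
               tolerance = 1e-12)
  expect_equal(e$ka, 0)
})

test_that("ks_ng86 agrees with the pathway-enumeration oracle on random pairs", {
  set.seed(19)
  sense <- oracle_sense_codons()
  for (r in 1:8) {
    a <- paste(sample(sense, 40L, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 40L, replace = TRUE), collapse = "")
    mine <- ks_ng86(a, b)
    orac <- oracle_ng86(a, b)
    expect_equal(mine$S, orac$S, tolerance = 1e-9)
    expect_equal(mine$Sd, orac$Sd, tolerance = 1e-9)
    expect_equal(mine$Nd, orac$Nd, tolerance = 1e-9)
    expect_equal(mine$ks, orac$ks, tolerance = 1e-9)
    expect_equal(mine$ka, orac$ka, tolerance = 1e-9)
  }
})

test_that("saturation is flagged, not fabricated", {
  # maximally divergent synonymous-free comparison: force high p_s by
  # pairing codons with all-different synonymous third positions is hard to
  # reach Ks saturation; construct artificially via many differences
  a <- paste(rep("TTA", 60L), collapse = "")
  b <- paste(rep("CTG", 60L), collapse = "")  # Leu vs Leu, 2 syn diffs each
  e <- ks_ng86(a, b)
  expect_true(e$saturated)
  expect_true(is.na(e$ks))
})

test_that("filter_ks keeps the stated closed interval and drops NA", {
  expect_equal(filter_ks(c(0.005, 0.01, 1.9, 2.0, 2.1)),
               c(0.01, 1.9, 2.0), ignore_attr = TRUE)
  expect_warning(out <- filter_ks(c(NA, NA)), "no Ks values")
  expect_length(out, 0L)
  expect_error(filter_ks(1, lo = 2, hi = 1), "exceed")
  set.seed(4)
  v <- c(stats::runif(200, 0, 3), NA, NA)
  got <- filter_ks(v, 0.01, 2.0)
  naive <- v[!is.na(v) & v >= 0.01 & v <= 2.0]
  expect_equal(as.numeric(got), naive)
  ret <- attr(got, "retention")
  expect_equal(unname(ret["kept"] + ret["dropped"]), length(v))
})

test_that("mixture: degenerate and single-cluster inputs select K = 1", {
  deg <- fit_ks_mixture(rep(0.25, 50L), seed = 1)
  expect_equal(deg$K, 1L)
  expect_true(deg$degenerate)
  set.seed(2)
  tight <- exp(rnorm(300, log(0.2), 0.05))
  fit <- fit_ks_mixture(tight, k = 1:3, n_restarts = 3, seed = 1)
  expect_equal(fit$K, 1L)
  expect_error(fit_ks_mixture(c(1, 2, 3), seed = 1), "at least 10")
  expect_error(fit_ks_mixture(c(rep(1, 20), -1), seed = 1), "positive")
})

test_that("ICL equals BIC minus twice the recomputed entropy", {
  set.seed(5)
  v <- exp(c(rnorm(400, log(0.05), 0.3), rnorm(400, log(1), 0.3)))
  fit <- fit_ks_mixture(v, k = 2L, n_restarts = 3, seed = 2)
  f2 <- fit$fits[["K2"]]
  # independent responsibility recomputation
  x <- log(v)
  dens <- vapply(1:2, function(j)
    f2$pi[j] * dnorm(x, f2$mu[j], f2$sigma[j]), numeric(length(x)))
  z <- dens / rowSums(dens)
  ent <- -sum(z * log(z))
  expect_equal(f2$ICL, f2$BIC - 2 * ent, tolerance = 1e-6)
  expect_equal(f2$BIC, 2 * f2$logL - (3 * 2 - 1) * log(length(v)),
               tolerance = 1e-9)
})

test_that("mixture agrees with mclust on a well-separated sample", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its package attached
  set.seed(6)
  v <- exp(c(rnorm(500, log(0.03), 0.25), rnorm(500, log(1.2), 0.25)))
  fit <- fit_ks_mixture(v, k = 2L, n_restarts = 5, seed = 3)
  mc <- mclust::Mclust(log(v), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$logL, mc$loglik, tolerance = 1e-3)
  expect_equal(sort(fit$mu_log), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("responsibilities, density, and simulate are coherent", {
  set.seed(7)
  v <- exp(c(rnorm(300, log(0.05), 0.3), rnorm(300, log(1), 0.3)))
  fit <- fit_ks_mixture(v, k = 2L, n_restarts = 3, seed = 4)
  z <- predict(fit, type = "responsibility")
  expect_equal(rowSums(z), rep(1, length(v)), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # density integrates to ~1 on the Ks scale
  grid <- exp(seq(log(1e-4), log(20), length.out = 4000L))
  dens <- predict(fit, grid)
  expect_equal(sum(dens[-1] * diff(grid)), 1, tolerance = 0.01)
  sims <- simulate(fit, 2000L, seed = 9)
  expect_true(all(sims > 0))
})

test_that("primary component tracks the modal peak with low-mean tie-break", {
  set.seed(8)
  v <- exp(c(rnorm(1500, log(0.05), 0.25), rnorm(300, log(1.5), 0.25)))
  fit <- fit_ks_mixture(v, k = 2L, n_restarts = 3, seed = 5)
  pc <- select_primary_component(fit)
  expect_equal(pc$component, 1L)
  expect_lt(abs(pc$mean_ks - 0.05), 0.02)

  k1 <- fit_ks_mixture(exp(rnorm(200, log(0.2), 0.1)), k = 1L,
                       n_restarts = 2, seed = 6)
  expect_equal(select_primary_component(k1)$component, 1L)

  # symmetric tie: equidistant means resolve to the smaller one
  fake <- structure(list(log_ks = rep(0, 100L), mu_log = c(-1, 1),
                         mean_ks = exp(c(-1, 1))), class = "ks_mixture")
  expect_equal(select_primary_component(fake, values = rep(0, 100L))$component,
               1L)
})

test_that("divergence_time implements T = Ks / (2 lambda) and validates", {
  expect_equal(divergence_time(0, 6.1e-9)$t_mya, 0)
  dt <- divergence_time(0.3, 1e-9)
  expect_equal(dt$t_mya, 0.3 / (2 * 1e-9) / 1e6)
  # linear in ks, inverse-linear in lambda
  expect_equal(divergence_time(0.6, 1e-9)$t_mya, 2 * dt$t_mya)
  expect_equal(divergence_time(0.3, 2e-9)$t_mya, dt$t_mya / 2)
  expect_error(divergence_time(-1, 1e-9), "non-negative")
  expect_error(divergence_time(0.1, 0), "positive")
})

test_that("clock LRT: statistic, chi-squared tail, and nesting violation", {
  eq <- clock_lrt(-100, -100, df = 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  crit <- clock_lrt(-100, -100 + 3.841459 / 2, df = 1)
  expect_equal(crit$p, 0.05, tolerance = 1e-4)
  expect_equal(crit$p, pchisq(3.841459, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_warning(bad <- clock_lrt(-99, -100, df = 1), "negative")
  expect_true(bad$nesting_violation)
  expect_lt(bad$statistic, 0)
})

test_that("EM log-likelihood is non-decreasing (internal assertion holds)", {
  set.seed(11)
  for (r in 1:5) {
    v <- exp(rnorm(200, sample(c(-3, -1, 0), 1L), runif(1, 0.2, 0.6)))
    expect_no_error(fit_ks_mixture(v, k = 1:3, n_restarts = 2, seed = r))
  }
})
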