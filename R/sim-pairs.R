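# Codon-aligned sequence pairs diverged to target Ks values drawn from a
# log-normal mixture. Divergence is realised by applying synonymous
# single-base substitutions (verified against the standard genetic code)
# until the NG86 estimate of the pair reaches the target, so the estimator's
# input matches its model without a full codon-substitution simulator.

#' Default Ks mixture components for divergent-pair simulation
#'
#' Three log-normal components centred at Ks 0.027, 0.251 and 1.616 — the
#' recent duplication, older WGD, and ancient/saturating peaks typical of a
#' paleopolyploid Cannabaceae genome — with 0.35 ln-unit spreads and
#' 0.3/0.5/0.2 weights.
#'
#' @return `data.frame` with columns `mean_ks`, `sd_log`, `weight`.
#' @export
default_ks_components <- function() {
  data.frame(mean_ks = c(0.027, 0.251, 1.616),
             sd_log = c(0.35, 0.35, 0.35),
             weight = c(0.3, 0.5, 0.2))
}

# Largest Ks the generator will aim for; beyond this p_s is so close to the
# JC saturation bound (3/4) that the target is unreachable on finite sites.
.ks_saturation_bound <- function() jc_correct(0.72)

#' Simulate codon-aligned CDS pairs at mixture-drawn Ks values
#'
#' For each pair, a random ancestral in-frame sequence of sense codons is
#' drawn, `log(Ks_true)` is sampled from the component mixture, and the
#' derived copy accumulates synonymous substitutions (a random codon
#' position, then a uniform choice among single-base changes that preserve
#' the encoded amino acid and avoid stops) until the realised NG86 Ks of the
#' pair first reaches the target. No stop codons are ever introduced and the
#' two sequences stay equal-length and in frame.
#'
#' Components whose mean exceeds the saturation bound (p_s >= 3/4 would be
#' required) are an error; individual mixture draws beyond the bound are
#' truncated to it and counted in `n_truncated`.
#'
#' @param seed Global seed (fixed-offset child stream).
#' @param n_pairs Number of pairs.
#' @param ks_components `data.frame` with columns `mean_ks`, `sd_log`,
#'   `weight` (weights must sum to 1); defaults to
#'   [default_ks_components()].
#' @param codon_length Codons per sequence (>= 50).
#' @return List of class `divergent_pairs`: `pairs` (list of
#'   `list(id, seq_a, seq_b)`), and `truth` (`data.frame` with `pair_id`,
#'   `component`, `ks_target`, `ks_realized`), plus attribute
#'   `n_truncated`.
#' @examples
#' dp <- simulate_divergent_pairs(seed = 1, n_pairs = 3,
#'   ks_components = data.frame(mean_ks = 0.1, sd_log = 0, weight = 1),
#'   codon_length = 100)
#' dp$truth
#' @export
simulate_divergent_pairs <- function(seed, n_pairs,
                                     ks_components = default_ks_components(),
                                     codon_length = 300L) {
  stopifnot(n_pairs >= 1L, codon_length >= 50L)
  kc <- ks_components
  if (!all(c("mean_ks", "sd_log", "weight") %in% names(kc))) {
    stop("ks_components needs columns mean_ks, sd_log, weight")
  }
  if (abs(sum(kc$weight) - 1) > 1e-9) stop("component weights must sum to 1")
  if (any(kc$mean_ks < 0) || any(kc$sd_log < 0)) {
    stop("component means and sds must be non-negative")
  }
  bound <- .ks_saturation_bound()
  if (any(kc$mean_ks > bound)) {
    stop("component mean Ks ", max(kc$mean_ks),
         " exceeds the saturation bound (", round(bound, 3),
         "): p_s >= 3/4 is unreachable under the JC correction")
  }
  set.seed(child_seed(seed, "pairs"))
  tabs <- ng86_tables()
  # ancestral codons drawn from sense codons with >=0 synonymous options
  cod_pool <- tabs$codons

  comp <- sample.int(nrow(kc), n_pairs, replace = TRUE, prob = kc$weight)
  ks_target <- ifelse(
    kc$sd_log[comp] == 0, kc$mean_ks[comp],
    exp(stats::rnorm(n_pairs, log(pmax(kc$mean_ks[comp], 1e-12)),
                     kc$sd_log[comp])))
  ks_target[kc$mean_ks[comp] == 0] <- 0
  n_trunc <- sum(ks_target > bound)
  ks_target <- pmin(ks_target, bound)

  pairs <- vector("list", n_pairs)
  realized <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- sample(cod_pool, codon_length, replace = TRUE)
    res <- .diverge_to_ks(anc, ks_target[i], tabs)
    pairs[[i]] <- list(id = sprintf("pair_%05d", i),
                       seq_a = paste(anc, collapse = ""),
                       seq_b = paste(res$codons, collapse = ""))
    realized[i] <- res$ks
  }
  structure(list(
    pairs = pairs,
    truth = data.frame(pair_id = vapply(pairs, `[[`, character(1), "id"),
                       component = comp,
                       ks_target = ks_target,
                       ks_realized = realized,
                       stringsAsFactors = FALSE)
  ), class = "divergent_pairs", n_truncated = n_trunc)
}

# Mutate `der` (starting as a copy of `anc`) with synonymous single-base
# steps until the pairwise NG86 Ks first reaches `target`. Totals are
# maintained incrementally: one codon changes per event.
.diverge_to_ks <- function(anc, target, tabs) {
  L <- length(anc)
  der <- anc
  ia <- match(anc, tabs$codons)
  ib <- ia
  site_a <- tabs$sites[ia]
  S_tot <- sum(site_a)  # sites averaged over the two sequences
  Sd_tot <- 0
  ks <- 0
  if (target <= 0) return(list(codons = der, ks = 0))
  max_events <- 80L * L
  ev <- 0L
  while (ks < target && ev < max_events) {
    ev <- ev + 1L
    pos <- sample.int(L, 1L)
    nb <- tabs$syn_neighbours[[ib[pos]]]
    if (length(nb) == 0L) next
    new_cod <- nb[sample.int(length(nb), 1L)]
    new_ib <- match(new_cod, tabs$codons)
    # update running site and difference totals for this codon only
    old_pair_S <- (site_a[pos] + tabs$sites[ib[pos]]) / 2
    new_pair_S <- (site_a[pos] + tabs$sites[new_ib]) / 2
    S_tot <- S_tot - old_pair_S + new_pair_S
    Sd_tot <- Sd_tot - tabs$sd[ia[pos], ib[pos]] + tabs$sd[ia[pos], new_ib]
    ib[pos] <- new_ib
    der[pos] <- new_cod
    ps <- if (S_tot > 0) Sd_tot / S_tot else 0
    ks <- if (ps >= 0.75) Inf else -0.75 * log(1 - 4 * ps / 3)
  }
  ps <- if (S_tot > 0) Sd_tot / S_tot else 0
  list(codons = der, ks = jc_correct(min(ps, 0.749999)))
}
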