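# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: translation
# goes through seqinr, enumerations are naive/recursive, counts are per-base
# loops.

# --- codon translation independent of Biostrings ---------------------------
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_sense_codons <- function() {
  b <- c("T", "C", "A", "G")
  cods <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
                function(r) paste(r, collapse = ""))
  cods[vapply(cods, oracle_translate, character(1)) != "*"]
}

# NG86 synonymous-site count of one codon: per position, the synonymous
# fraction among non-stop single-base changes.
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  spl <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    tot <- 0
    for (b in setdiff(bases, spl[pos])) {
      mut <- spl
      mut[pos] <- b
      maa <- oracle_translate(paste(mut, collapse = ""))
      if (maa == "*") next
      tot <- tot + 1
      if (maa == aa) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# Recursive pathway enumeration of syn/nonsyn differences between codons.
oracle_path_counts <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  paths <- list()
  recurse <- function(cur, syn, non, allow_stop) {
    diff <- which(cur != s2)
    if (length(diff) == 0L) {
      paths[[length(paths) + 1L]] <<- c(syn, non)
      return(invisible())
    }
    for (p in diff) {
      nxt <- cur
      nxt[p] <- s2[p]
      aa1 <- oracle_translate(paste(cur, collapse = ""))
      aa2 <- oracle_translate(paste(nxt, collapse = ""))
      if (aa2 == "*" && !allow_stop) next
      is_syn <- (aa1 == aa2 && aa2 != "*")
      recurse(nxt, syn + is_syn, non + !is_syn, allow_stop)
    }
  }
  recurse(s1, 0L, 0L, allow_stop = FALSE)
  if (length(paths) == 0L) recurse(s1, 0L, 0L, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# Full NG86 estimate of a codon-aligned pair, assembled from the oracles.
oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  sense <- oracle_sense_codons()
  ok <- ca %in% sense & cb %in% sense
  ca <- ca[ok]
  cb <- cb[ok]
  S <- sum((vapply(ca, oracle_syn_sites, numeric(1)) +
              vapply(cb, oracle_syn_sites, numeric(1))) / 2)
  d <- mapply(function(x, y) oracle_path_counts(x, y), ca, cb)
  Sd <- sum(d["syn", ])
  Nd <- sum(d["nonsyn", ])
  N <- 3 * length(ca) - S
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(ps), ka = jc(pn), S = S, N = N, Sd = Sd, Nd = Nd)
}

# --- brute-force longest collinear chain (both orientations) ---------------
oracle_longest_chain <- function(ra, rb, max_gap) {
  m <- length(ra)
  best <- 0L
  extend <- function(last, remaining, len, rbs) {
    best <<- max(best, len)
    for (i in remaining) {
      if (ra[i] > ra[last] && rbs[i] > rbs[last] &&
          ra[i] - ra[last] <= max_gap && rbs[i] - rbs[last] <= max_gap) {
        extend(i, setdiff(remaining, i), len + 1L, rbs)
      }
    }
  }
  for (rbs in list(rb, -rb)) {
    for (i in seq_len(m)) extend(i, setdiff(seq_len(m), i), 1L, rbs)
  }
  best
}

# --- brute-force BH step-up q-values ---------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    idx <- ord[i]
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[idx] <- min(1, min(cand))
  }
  q
}

# --- hypergeometric upper tail from the choose() pmf -----------------------
oracle_hyper_upper <- function(k, K, M, n) {
  kk <- max(0L, k):min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# --- naive overlapping-window word counter (N windows skipped) -------------
oracle_word_counts <- function(seqs, width) {
  counts <- integer(0)
  for (s in seqs) {
    n <- nchar(s)
    for (i in seq_len(n - width + 1L)) {
      w <- substr(s, i, i + width - 1L)
      if (grepl("[^ACGT]", w)) next
      counts[w] <- (if (is.na(counts[w])) 0L else counts[w]) + 1L
    }
  }
  counts
}

# --- O(n^2) exon-overlap merge oracle --------------------------------------
oracle_merge_kept <- function(primary, secondary) {
  sec_ids <- unique(secondary$gene_id)
  dropped <- character(0)
  for (sid in sec_ids) {
    se <- secondary[secondary$gene_id == sid, ]
    hit <- FALSE
    for (i in seq_len(nrow(se))) {
      for (j in seq_len(nrow(primary))) {
        if (se$scaffold[i] == primary$scaffold[j] &&
            se$strand[i] == primary$strand[j] &&
            se$start[i] <= primary$end[j] &&
            primary$start[j] <= se$end[i]) {
          hit <- TRUE
        }
      }
    }
    if (hit) dropped <- c(dropped, sid)
  }
  setdiff(sec_ids, dropped)
}

# --- per-base bitmap coverage of intervals ---------------------------------
oracle_interval_coverage <- function(gaps, repeats) {
  if (nrow(gaps) == 0L) return(0L)
  lo <- min(gaps$start)
  hi <- max(gaps$end)
  in_gap <- logical(hi - lo + 1L)
  for (i in seq_len(nrow(gaps))) {
    in_gap[(gaps$start[i]:gaps$end[i]) - lo + 1L] <- TRUE
  }
  covered <- logical(hi - lo + 1L)
  for (i in seq_len(NROW(repeats))) {
    st <- max(lo, repeats$start[i])
    en <- min(hi, repeats$end[i])
    if (en >= st) covered[(st:en) - lo + 1L] <- TRUE
  }
  sum(in_gap & covered)
}

# random gene-model exon table for merge tests
random_gene_models <- function(n, prefix, scaffolds = c("s1", "s2"),
                               max_pos = 5000L) {
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:3, 1L)
    st <- sort(sample.int(max_pos, n_ex))
    len <- sample(20:80, n_ex, replace = TRUE)
    en <- st + len
    # enforce non-overlapping sorted exons
    for (j in seq_len(n_ex)[-1L]) {
      if (st[j] <= en[j - 1L]) st[j] <- en[j - 1L] + sample(1:20, 1L)
      en[j] <- st[j] + len[j]
    }
    data.frame(gene_id = sprintf("%s_%03d", prefix, i),
               scaffold = sample(scaffolds, 1L),
               start = st, end = en,
               strand = sample(c("+", "-"), 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
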