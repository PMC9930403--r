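# Ingestion of yn00 (PAML) result tables, so externally computed
# transition/transversion- and codon-frequency-weighted estimates can be
# substituted for the built-in NG86 estimator in the mixture stage.

#' Read pairwise dS/dN estimates from a yn00 output file
#'
#' Scans a yn00 result file (the `(B) Yang & Nielsen (2000) method`
#' pairwise section, or any line carrying `dS =`/`dN =` style fields) and
#' returns one row per sequence pair. The parser is deliberately tolerant:
#' it keys on the `dN =`, `dS =`, `S =`, `N =`, `omega`/`dN/dS` tokens that
#' are stable across yn00 versions rather than on column positions.
#'
#' @param path yn00 output file (e.g. `yn.out`... the main result file).
#' @return `data.frame` with columns `pair_id` (`seqA-seqB` when sequence
#'   indices/names are present, otherwise a running index), `ks` (dS),
#'   `ka` (dN), `S`, `N`, `omega`. Compatible with [filter_ks()] and
#'   [fit_ks_mixture()].
#' @export
read_yn00 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(ln, key) {
    m <- regmatches(ln, regexec(paste0(key,
                                       "\\s*=\\s*(-?[0-9.]+(e[+-]?\\d+)?)"),
                                ln, ignore.case = TRUE))[[1L]]
    if (length(m)) as.numeric(m[2L]) else NA_real_
  }
  rows <- list()
  for (ln in lines) {
    om <- grab(ln, "dN/dS")
    if (is.na(om)) om <- grab(ln, "omega")
    # strip the dN/dS field so its tail cannot shadow the dS field
    ln2 <- gsub("dN/dS\\s*=\\s*-?[0-9.eE+-]+", " ", ln)
    ds <- grab(ln2, "dS")
    dn <- grab(ln2, "dN")
    if (is.na(ds) || is.na(dn)) next
    s_sites <- grab(ln2, "\\bS")
    n_sites <- grab(ln2, "\\bN")
    idx <- regmatches(ln, regexec("^\\s*(\\S+)\\s+(\\S+)\\s", ln))[[1L]]
    pair_id <- if (length(idx) && !grepl("=", idx[2L]) &&
                   !grepl("=", idx[3L])) {
      paste0(idx[2L], "-", idx[3L])
    } else {
      sprintf("pair_%05d", length(rows) + 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pair_id, ks = ds, ka = dn, S = s_sites, N = n_sites,
      omega = om, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no pairwise dS/dN records found in ", path)
  }
  do.call(rbind, rows)
}
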