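# Finite Gaussian mixture on log-transformed Ks values, fitted by EM with
# unequal component variances and model selection by the integrated
# complete-data likelihood (ICL). This is the package's central model: peaks
# of the mixture mark whole-genome duplication or speciation events.

logsumexp_rows <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

# k-means++ style seeding of component centres.
kpp_centers <- function(x, K) {
  n <- length(x)
  centers <- numeric(K)
  centers[1] <- x[sample.int(n, 1L)]
  if (K > 1L) {
    for (j in 2:K) {
      d2 <- Reduce(pmin, lapply(centers[1:(j - 1L)], function(cc) (x - cc)^2))
      centers[j] <- if (sum(d2) <= 0) {
        x[sample.int(n, 1L)]
      } else {
        x[sample.int(n, 1L, prob = d2)]
      }
    }
  }
  sort(centers)
}

# One EM run from a given start. logL is asserted non-decreasing.
em_run <- function(x, pi0, mu0, sig0, tol, max_iter, var_floor) {
  n <- length(x)
  K <- length(mu0)
  pi_ <- pi0
  mu <- mu0
  sig <- sig0
  prev <- -Inf
  logL <- -Inf
  z <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(K),
                 function(j) log(pi_[j]) + stats::dnorm(x, mu[j], sig[j],
                                                        log = TRUE),
                 numeric(n))
    if (K == 1L) lp <- matrix(lp, ncol = 1L)
    lse <- logsumexp_rows(lp)
    logL <- sum(lse)
    stopifnot("EM log-likelihood decreased" =
                logL >= prev - 1e-6 * (abs(prev) + 1))
    z <- exp(lp - lse)
    if (is.finite(prev) && abs(logL - prev) < tol * (abs(logL) + 1e-12)) {
      converged <- TRUE
      break
    }
    prev <- logL
    nj <- pmax(colSums(z), 1e-12)
    pi_ <- nj / n
    mu <- colSums(z * x) / nj
    v <- colSums(z * (x - rep(mu, each = n))^2) / nj
    sig <- sqrt(pmax(v, var_floor))
  }
  list(pi = pi_, mu = mu, sigma = sig, logL = logL, z = z,
       iterations = iter, converged = converged)
}

em_fit_k <- function(x, K, n_restarts, tol, max_iter, var_floor) {
  n <- length(x)
  sx <- stats::sd(x)
  starts <- lapply(seq_len(max(1L, n_restarts)), function(r) {
    mu0 <- kpp_centers(x, K)
    assign_ <- apply(abs(outer(x, mu0, "-")), 1L, which.min)
    pi0 <- pmax(tabulate(assign_, K) / n, 1 / (10 * K))
    pi0 <- pi0 / sum(pi0)
    sig0 <- vapply(seq_len(K), function(j) {
      xi <- x[assign_ == j]
      s <- if (length(xi) > 1L) stats::sd(xi) else 0
      max(s, sx / (2 * K), sqrt(var_floor))
    }, numeric(1))
    list(pi = pi0, mu = mu0, sigma = sig0)
  })
  # short burn-in runs, then polish the best start to full tolerance
  short <- lapply(starts, function(s0) {
    em_run(x, s0$pi, s0$mu, s0$sigma, tol = 1e-6, max_iter = 200L,
           var_floor = var_floor)
  })
  best <- short[[which.max(vapply(short, `[[`, numeric(1), "logL"))]]
  fit <- em_run(x, best$pi, best$mu, best$sigma, tol = tol,
                max_iter = max_iter, var_floor = var_floor)

  ord <- order(fit$mu)
  fit$pi <- fit$pi[ord]
  fit$mu <- fit$mu[ord]
  fit$sigma <- fit$sigma[ord]
  fit$z <- fit$z[, ord, drop = FALSE]

  m <- 3 * K - 1
  entropy <- -sum(fit$z * log(pmax(fit$z, 1e-300)))
  fit$K <- K
  fit$df <- m
  fit$BIC <- 2 * fit$logL - m * log(n)
  fit$entropy <- entropy
  fit$ICL <- fit$BIC - 2 * entropy
  fit
}

#' Fit a Gaussian mixture to log-transformed Ks values
#'
#' Fits finite Gaussian mixtures with unequal variances to `log(Ks)` by EM,
#' for each component count in `k`, and selects the number of components by
#' maximising the integrated complete-data likelihood
#' `ICL = BIC - 2 * E`, where `E = -sum(z * log z)` is the classification
#' entropy of the fitted responsibilities and `BIC = 2 logL - (3K - 1) log n`.
#' ICL penalises strongly overlapping components and so prefers
#' well-separated peaks, the quantity of interest when reading duplication
#' or speciation events off a Ks distribution.
#'
#' Each fit takes the best of `n_restarts` k-means++-style initialisations
#' (short EM burn-in, then the best start is polished to convergence:
#' relative log-likelihood change below `tol` or `max_iter` iterations).
#' Component variances are floored at `var_floor`.
#'
#' @param ks Positive Ks values (numeric vector, or a data.frame with a
#'   `ks` column). Apply [filter_ks()] beforehand if the raw estimates may
#'   contain allelic-range or near-saturated values.
#' @param k Integer vector of candidate component counts (default `1:5`).
#' @param n_restarts Restarts per component count.
#' @param seed Integer seed controlling initialisation (mandatory for
#'   reproducible fits).
#' @param max_iter,tol EM stopping rule.
#' @param var_floor Lower bound on component variances (log-Ks scale).
#' @return Object of class `ks_mixture` with the selected fit promoted to
#'   top level: `K`, `weights`, `mu_log`, `sigma_log`, `mean_ks`
#'   (`exp(mu_log)`), `logL`, `BIC`, `ICL`, `z`, the per-K fit list `fits`,
#'   and the data (`ks`, `log_ks`, `n`).
#' @seealso [select_primary_component()], [divergence_time()],
#'   [simulate_divergent_pairs()]
#' @examples
#' set.seed(1)
#' ks <- exp(c(rnorm(300, log(0.03), 0.3), rnorm(300, log(1.5), 0.3)))
#' fit <- fit_ks_mixture(ks, k = 1:3, n_restarts = 3, seed = 1)
#' fit$K
#' @export
fit_ks_mixture <- function(ks, k = 1:5, n_restarts = 10, seed = 1,
                           max_iter = 1000L, tol = 1e-8, var_floor = 1e-6) {
  cl <- match.call()
  if (is.data.frame(ks)) ks <- ks$ks
  ks <- ks[is.finite(ks)]
  if (any(ks <= 0)) stop("all Ks values must be positive")
  n <- length(ks)
  if (n < 10L) stop("need at least 10 Ks values, got ", n)
  x <- log(ks)
  k <- sort(unique(as.integer(k)))

  degenerate <- stats::sd(x) == 0
  if (degenerate) k <- 1L

  set.seed(seed)
  fits <- lapply(k, function(K) {
    if (degenerate) {
      z <- matrix(1, n, 1L)
      fit <- list(pi = 1, mu = x[1], sigma = sqrt(var_floor),
                  logL = sum(stats::dnorm(x, x[1], sqrt(var_floor),
                                          log = TRUE)),
                  z = z, iterations = 0L, converged = TRUE, K = 1L,
                  df = 2, entropy = 0)
      fit$BIC <- 2 * fit$logL - 2 * log(n)
      fit$ICL <- fit$BIC
      return(fit)
    }
    if (K > length(unique(x))) return(NULL)
    em_fit_k(x, K, n_restarts, tol, max_iter, var_floor)
  })
  names(fits) <- paste0("K", k)
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  k <- k[keep]
  if (length(fits) == 0L) stop("no mixture could be fitted")

  icl <- vapply(fits, `[[`, numeric(1), "ICL")
  sel <- which.max(icl)  # ties resolve to the smaller K (k is ascending)
  best <- fits[[sel]]

  structure(list(
    call = cl,
    ks = ks, log_ks = x, n = n,
    k_range = k,
    fits = fits,
    K = best$K,
    weights = best$pi,
    mu_log = best$mu,
    sigma_log = best$sigma,
    mean_ks = exp(best$mu),
    logL = best$logL,
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    ICL = icl,
    entropy = best$entropy,
    z = best$z,
    converged = best$converged,
    degenerate = degenerate
  ), class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture on log(Ks): %d observations, K = %d selected by ICL\n",
    x$n, x$K))
  print(coef(x), digits = 4)
  cat(sprintf("logL = %.2f  BIC = %.2f  ICL = %.2f\n",
              x$logL, x$BIC[[paste0("K", x$K)]], x$ICL[[paste0("K", x$K)]]))
  invisible(x)
}

#' @export
summary.ks_mixture <- function(object, ...) {
  sel <- data.frame(K = object$k_range,
                    logL = vapply(object$fits, `[[`, numeric(1), "logL"),
                    BIC = object$BIC, ICL = object$ICL,
                    selected = object$k_range == object$K)
  out <- list(components = coef(object), selection = sel,
              primary = select_primary_component(object), n = object$n)
  class(out) <- "summary.ks_mixture"
  out
}

#' @export
print.summary.ks_mixture <- function(x, ...) {
  cat("Model selection over component counts (larger ICL preferred):\n")
  print(x$selection, digits = 6, row.names = FALSE)
  cat("\nComponents of the selected model (log-Ks scale and back-transformed):\n")
  print(x$components, digits = 4)
  cat(sprintf(
    "\nPrimary component (nearest the modal peak): %d, mean Ks = %.4g\n",
    x$primary$component, x$primary$mean_ks))
  invisible(x)
}

#' @export
coef.ks_mixture <- function(object, ...) {
  cbind(weight = object$weights, mean_log = object$mu_log,
        sd_log = object$sigma_log, mean_ks = object$mean_ks)
}

#' @export
logLik.ks_mixture <- function(object, ...) {
  structure(object$logL, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' Mixture density or component responsibilities for new Ks values
#'
#' @param object A fitted [fit_ks_mixture()] model.
#' @param newdata Positive Ks values; defaults to the training values.
#' @param type `"density"` for the mixture density (on the Ks scale by
#'   default), `"responsibility"` for the n x K posterior membership matrix.
#' @param scale For densities: `"ks"` transforms the log-scale density by
#'   the Jacobian `1/ks`; `"log"` returns the density of log(Ks).
#' @param ... Unused.
#' @export
predict.ks_mixture <- function(object, newdata = NULL,
                               type = c("density", "responsibility"),
                               scale = c("ks", "log"), ...) {
  type <- match.arg(type)
  scale <- match.arg(scale)
  v <- if (is.null(newdata)) object$ks else newdata
  if (any(v <= 0)) stop("Ks values must be positive")
  x <- log(v)
  lp <- vapply(seq_len(object$K), function(j) {
    log(object$weights[j]) +
      stats::dnorm(x, object$mu_log[j], object$sigma_log[j], log = TRUE)
  }, numeric(length(x)))
  if (object$K == 1L) lp <- matrix(lp, ncol = 1L)
  lse <- logsumexp_rows(lp)
  if (type == "responsibility") return(exp(lp - lse))
  dens <- exp(lse)
  if (scale == "ks") dens <- dens / v
  dens
}

#' Simulate Ks values from a fitted mixture
#'
#' @param object A fitted [fit_ks_mixture()] model.
#' @param nsim Number of values to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of simulated Ks values.
#' @export
simulate.ks_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  exp(stats::rnorm(nsim, object$mu_log[comp], object$sigma_log[comp]))
}

#' Plot a fitted log-Ks mixture over the data histogram
#'
#' Histogram of log(Ks) with the mixture density superimposed and dashed
#' vertical lines at the component means. If `lambda` is given, each mean is
#' annotated with the corresponding divergence time T = Ks/(2 lambda).
#'
#' @param x A fitted [fit_ks_mixture()] model.
#' @param breaks Passed to [graphics::hist()].
#' @param lambda Optional substitution rate (subs/site/year) for time labels.
#' @param main,xlab Plot annotation.
#' @param ... Further arguments to [graphics::hist()].
#' @export
plot.ks_mixture <- function(x, breaks = "FD", lambda = NULL,
                            main = "log(Ks) distribution",
                            xlab = "log(Ks)", ...) {
  h <- graphics::hist(x$log_ks, breaks = breaks, freq = FALSE,
                      main = main, xlab = xlab,
                      col = "grey85", border = "grey60", ...)
  xs <- seq(min(x$log_ks), max(x$log_ks), length.out = 512L)
  dens <- rowSums(vapply(seq_len(x$K), function(j) {
    x$weights[j] * stats::dnorm(xs, x$mu_log[j], x$sigma_log[j])
  }, numeric(length(xs))))
  graphics::lines(xs, dens, lwd = 2, col = "steelblue4")
  graphics::abline(v = x$mu_log, lty = 2, col = "firebrick")
  if (!is.null(lambda)) {
    lab <- sprintf("%.2f mya", divergence_time(x$mean_ks, lambda)$t_mya)
    graphics::mtext(lab, at = x$mu_log, side = 3, cex = 0.7,
                    col = "firebrick")
  }
  invisible(h)
}

#' Identify the component nearest the modal peak
#'
#' The modal peak is the midpoint of the highest-count histogram bin of
#' log(Ks), with the bin width chosen by the Freedman-Diaconis rule (the
#' width used is reported). The primary component is the one whose log-scale
#' mean is nearest that mode; ties go to the smaller mean. In a Ks analysis
#' this component is read as the primary putative duplication or speciation
#' event.
#'
#' @param object A fitted [fit_ks_mixture()] model.
#' @param values Optional log-Ks values to form the histogram from
#'   (defaults to the training data).
#' @return List with `component` (index into the mean-sorted components),
#'   `mean_ks`, `mode_log` and `bin_width`.
#' @export
select_primary_component <- function(object, values = NULL) {
  x <- if (is.null(values)) object$log_ks else values
  n <- length(x)
  h <- 2 * stats::IQR(x) / n^(1 / 3)
  if (!is.finite(h) || h <= 0) h <- max(diff(range(x)) / 30, 1e-6)
  lo <- min(x) - h / 2
  breaks <- seq(lo, max(x) + h, by = h)
  ct <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mode_log <- ct$mids[which.max(ct$counts)]  # ties: lowest bin
  d <- abs(object$mu_log - mode_log)
  j <- which(d == min(d))[1L]  # components are mean-sorted: tie -> smaller mu
  list(component = j, mean_ks = object$mean_ks[j], mode_log = mode_log,
       bin_width = h)
}

#' Convert Ks to divergence time (T = Ks / 2 lambda)
#'
#' Under an approximately constant synonymous substitution rate `lambda`
#' (substitutions per synonymous site per year), two sequences that diverged
#' T years ago accumulate Ks = 2 lambda T synonymous substitutions per site,
#' so T = Ks / (2 lambda). Vectorised over both arguments, so a vector of
#' `lambda` values produces a rate-sensitivity table.
#'
#' @param ks Non-negative Ks value(s).
#' @param lambda Positive substitution rate(s), subs/site/year.
#' @return `data.frame` (class `divergence_time`) with columns `ks`,
#'   `lambda`, `t_years`, `t_mya`.
#' @examples
#' divergence_time(0.195, c(6.1e-9, 2.1e-9, 1.23e-9))
#' @export
divergence_time <- function(ks, lambda) {
  if (any(ks < 0)) stop("ks must be non-negative")
  if (any(lambda <= 0)) stop("lambda must be positive")
  n <- max(length(ks), length(lambda))
  ks <- rep_len(ks, n)
  lambda <- rep_len(lambda, n)
  t_years <- ks / (2 * lambda)
  structure(data.frame(ks = ks, lambda = lambda, t_years = t_years,
                       t_mya = t_years / 1e6),
            class = c("divergence_time", "data.frame"))
}

#' Likelihood-ratio test between strict and relaxed molecular clocks
#'
#' Computes `LRT = -2 (ln Ls - ln Lg)` for a strict clock (log-likelihood
#' `lnLs`) nested in a relaxed clock (`lnLg`), with an upper-tail chi-squared
#' p-value on `df` degrees of freedom. A negative statistic (relaxed fitting
#' worse than strict, impossible under exact nesting) is reported as-is with
#' a warning flag rather than clamped.
#'
#' @param lnLs,lnLg Finite log-likelihoods of the strict and relaxed models.
#' @param df Degrees of freedom (>= 1).
#' @return Object of class `clock_lrt`: `statistic`, `df`, `p`,
#'   `nesting_violation`.
#' @examples
#' clock_lrt(-1000, -998.1, df = 1)
#' @export
clock_lrt <- function(lnLs, lnLg, df = 1L) {
  stopifnot(is.finite(lnLs), is.finite(lnLg), df >= 1)
  stat <- -2 * (lnLs - lnLg)
  viol <- stat < 0
  if (viol) {
    warning("negative LRT statistic: relaxed model has lower likelihood ",
            "than the strict clock it nests")
  }
  structure(list(lnLs = lnLs, lnLg = lnLg, statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 nesting_violation = viol),
            class = "clock_lrt")
}

#' @export
print.clock_lrt <- function(x, ...) {
  cat("Molecular clock likelihood-ratio test\n")
  cat(sprintf("  LRT = %.4f on %d df, p = %.4g\n", x$statistic, x$df, x$p))
  if (x$nesting_violation) cat("  [nesting violation: statistic < 0]\n")
  invisible(x)
}
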