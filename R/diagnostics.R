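# Convergence diagnostics: spectral variance-of-mean estimation, the Geweke
# mean-comparison test (within-chain and between-run modes), the
# (multivariate) Gelman-Rubin-Brooks diagnostic, automatic burn-in
# estimation by a sequence of Geweke tests with Bonferroni-Holm correction,
# and Sokal's adaptive truncated autocorrelation-time estimator with the
# effective sample size.

#' Spectral estimate of the variance of a sample mean
#'
#' Estimates `Var(mean(x))` accounting for autocorrelation through the
#' spectral density at frequency zero, estimated from a fitted
#' autoregressive process (`S(0) / n` with
#' `S(0) = sigma2_pred / (1 - sum(phi))^2`). For i.i.d. input this
#' approaches `var(x)/n`; for an AR(1) process with coefficient `rho` it
#' approaches `var(x) * ((1+rho)/(1-rho)) / n`.
#'
#' @param x numeric series (length >= 10).
#' @return the variance-of-mean estimate; `0` with attribute
#'   `constant = TRUE` for a constant series.
#' @export
spectral_variance <- function(x) {
  n <- length(x)
  if (n < 10) stop("series too short for a spectral variance estimate")
  if (stats::var(x) == 0)
    return(structure(0, constant = TRUE))
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(n - 1L, floor(10 * log10(n)))),
    error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x) / n)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  s0 / n
}

#' Geweke mean-comparison test
#'
#' Compares the means of two segments of a chain (by default the first
#' `frac_a` against the last `frac_b` of the iterations), standardized by
#' the spectral variance-of-mean estimates:
#' `z = (mean_a - mean_b) / sqrt(sv_a + sv_b)` per parameter, with
#' two-sided normal p-values. In between-run mode (`chain_b` supplied) the
#' two "signals" are the two whole traces, which is the pairwise-similarity
#' usage.
#'
#' @param chain numeric matrix (iterations x parameters) or vector.
#' @param frac_a,frac_b segment fractions for the within-chain mode.
#' @param chain_b optional second chain for the between-run mode.
#' @return a list of class `geweke_result` with `z`, `p` (per parameter)
#'   and the segment definition.
#' @export
geweke_test <- function(chain, frac_a = 0.1, frac_b = 0.5, chain_b = NULL) {
  chain <- as.matrix(chain)
  if (is.null(chain_b)) {
    n <- nrow(chain)
    na <- floor(frac_a * n); nb <- floor(frac_b * n)
    if (na < 10 || nb < 10) stop("chain too short for the requested segments")
    a <- chain[seq_len(na), , drop = FALSE]
    b <- chain[(n - nb + 1):n, , drop = FALSE]
    segments <- list(mode = "within", frac_a = frac_a, frac_b = frac_b)
  } else {
    a <- chain
    b <- as.matrix(chain_b)
    if (ncol(a) != ncol(b)) stop("chains must have the same parameter count")
    segments <- list(mode = "between")
  }
  d <- ncol(a)
  z <- numeric(d)
  for (j in seq_len(d)) {
    sva <- spectral_variance(a[, j])
    svb <- spectral_variance(b[, j])
    if (sva == 0 && svb == 0) {
      if (mean(a[, j]) == mean(b[, j])) { z[j] <- 0; next }
      stop("degenerate (constant) segments with different means")
    }
    z[j] <- (mean(a[, j]) - mean(b[, j])) / sqrt(sva + svb)
  }
  names(z) <- colnames(chain)
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)), segments = segments),
            class = "geweke_result")
}

#' Gelman-Rubin-Brooks diagnostic
#'
#' Computes per-parameter potential scale reduction factors from the
#' within-chain (`W`) and between-chain (`B`) variances, and the
#' multivariate PSRF
#' `mpsrf = (n-1)/n + ((m+1)/m) * lambda_1` with `lambda_1` the largest
#' eigenvalue of `W^-1 B / n`.
#'
#' @param chains a list of >= 2 aligned trace matrices (equal dimensions).
#' @return a list of class `grb_result` with `psrf`, `mpsrf`, `n_chains`,
#'   `n_iter`.
#' @export
grb_diagnostic <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]]); d <- ncol(chains[[1]])
  if (!all(vapply(chains, function(c) nrow(c) == n && ncol(c) == d, TRUE)))
    stop("chains must have equal dimensions")
  m <- length(chains)
  means <- matrix(t(vapply(chains, colMeans, numeric(d))), nrow = m)
  covs <- lapply(chains, stats::cov)
  W <- Reduce(`+`, covs) / m
  Bn <- stats::cov(means) # = B / n
  if (any(diag(W) == 0)) stop("zero within-chain variance")
  psrf <- sqrt((m + 1) / m * ((n - 1) / n + diag(Bn) / diag(W)) -
                 (n - 1) / (m * n))
  lam <- tryCatch({
    ev <- eigen(solve(W, Bn), only.values = TRUE)$values
    max(Re(ev))
  }, error = function(e) NA_real_)
  mpsrf <- (n - 1) / n + (m + 1) / m * lam
  names(psrf) <- colnames(chains[[1]])
  structure(list(psrf = psrf, mpsrf = mpsrf, n_chains = m, n_iter = n),
            class = "grb_result")
}

#' Automatic burn-in estimation
#'
#' Runs the Geweke test on the chain truncated at each of `n_candidates`
#' equispaced candidate points (0%, 5%, ..., 95% of the iterations), with
#' the per-parameter p-values corrected by Bonferroni-Holm at level
#' `alpha`. The burn-in `n_BI` is the first candidate at which all
#' corrected tests pass; when no candidate passes the run is flagged
#' non-converged and `n_BI` equals the chain length (nothing usable
#' remains).
#'
#' @param chain trace matrix (iterations x parameters).
#' @param alpha test level.
#' @param n_candidates number of equispaced truncation candidates.
#' @param frac_a,frac_b Geweke segment fractions.
#' @return a list of class `burnin_result` with `n_bi`, `converged`, and
#'   the per-candidate outcomes.
#' @export
estimate_burnin <- function(chain, alpha = 0.05, n_candidates = 20,
                            frac_a = 0.1, frac_b = 0.5) {
  chain <- as.matrix(chain)
  n <- nrow(chain)
  if (n < 10 * n_candidates) stop("chain too short for burn-in estimation")
  cands <- floor(n * seq(0, 0.95, length.out = n_candidates))
  outcomes <- logical(n_candidates)
  n_bi <- n
  converged <- FALSE
  for (k in seq_along(cands)) {
    sub <- chain[(cands[k] + 1):n, , drop = FALSE]
    gw <- tryCatch(geweke_test(sub, frac_a, frac_b), error = function(e) NULL)
    pass <- !is.null(gw) && all(stats::p.adjust(gw$p, "holm") >= alpha)
    outcomes[k] <- pass
    if (pass) { n_bi <- cands[k]; converged <- TRUE; break }
  }
  structure(list(n_bi = n_bi, converged = converged,
                 candidates = cands, outcomes = outcomes),
            class = "burnin_result")
}

#' Integrated autocorrelation time (Sokal's estimator)
#'
#' `tau = 1 + 2 * sum_{k <= W} rho(k)` with the autocorrelation computed
#' via FFT of the mean-removed, zero-padded series and the truncation
#' window `W` chosen adaptively as the smallest `W` with
#' `W >= c * tau(W)`. The returned value is floored at 1.
#'
#' @param x numeric series (length >= 100).
#' @param c window constant (default 6).
#' @return the integrated autocorrelation time.
#' @export
autocorr_time_sokal <- function(x, c = 6) {
  n <- length(x)
  if (n < 100) stop("series too short for the autocorrelation-time estimate")
  if (stats::var(x) == 0) stop("constant series has no autocorrelation time")
  rho <- acf_fft(x)
  taus <- 1 + 2 * cumsum(rho[-1])
  W <- which(seq_along(taus) >= c * taus)
  W <- if (length(W)) W[1] else length(taus)
  max(1, taus[W])
}

# Autocorrelation function via FFT with zero padding.
acf_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, npad - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
  ac / ac[1]
}

#' Effective sample size (max autocorrelation-time rule)
#'
#' `ESS = N / max_i tau_i`, where `tau_i` is the per-parameter integrated
#' autocorrelation time — the maximum over parameters is taken because the
#' estimator is univariate. Apply to a trace with the burn-in removed.
#'
#' @param trace matrix (iterations x parameters) or vector.
#' @param c Sokal window constant.
#' @return a list with `ess`, per-parameter `tau`, and the implied
#'   thinning stride `ceiling(max(tau))`.
#' @export
effective_sample_size <- function(trace, c = 6) {
  trace <- as.matrix(trace)
  n <- nrow(trace)
  tau <- apply(trace, 2, autocorr_time_sokal, c = c)
  list(ess = n / max(tau), tau = tau, thin = ceiling(max(tau)))
}

#' Flat diagnostics report for one run
#'
#' Burn-in, convergence flag, per-parameter autocorrelation times and ESS
#' for a single sampler run, as a flat list suitable for JSON export.
#'
#' @param run a [run_sampler()] result (or a trace matrix).
#' @param alpha burn-in test level.
#' @return a list with `n_bi`, `converged`, `tau`, `ess`, `ess_per_second`.
#' @export
diagnose_run <- function(run, alpha = 0.05) {
  trace <- if (inherits(run, "sampler_run")) run$trace else as.matrix(run)
  bi <- estimate_burnin(trace, alpha = alpha)
  post <- trace[(bi$n_bi + 1):nrow(trace), , drop = FALSE]
  if (bi$converged && nrow(post) >= 100) {
    es <- tryCatch(effective_sample_size(post), error = function(e) NULL)
    ess <- if (is.null(es)) 0 else es$ess
    tau <- if (is.null(es)) rep(NA_real_, ncol(trace)) else es$tau
  } else {
    ess <- 0; tau <- rep(NA_real_, ncol(trace))
  }
  cpu <- if (inherits(run, "sampler_run")) run$cpu_seconds else NA_real_
  list(n_bi = bi$n_bi, converged = bi$converged, tau = as.numeric(tau),
       ess = ess,
       ess_per_second = if (is.finite(cpu) && cpu > 0) ess / cpu else NA_real_)
}
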