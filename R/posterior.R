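# Posterior evaluation: uniform box prior, Gaussian likelihood, tempering,
# and sensitivities (gradient + Fisher information) of the log-posterior.

#' Log-prior of a benchmark problem
#'
#' The priors are uniform on the box `[theta_min, theta_max]` (closed at both
#' boundaries). The normalization constant is dropped: the value is `0`
#' inside the box and `-Inf` outside, so reported log-posteriors are
#' comparable within a problem but not across problems.
#'
#' @param problem a [benchmark_problem()].
#' @param theta parameter vector on the sampling scale.
#' @return `0` or `-Inf`.
#' @export
log_prior <- function(problem, theta) {
  stopifnot(length(theta) == n_par(problem))
  if (all(is.finite(theta)) &&
      all(theta >= problem$theta_min & theta <= problem$theta_max)) 0 else -Inf
}

#' Log-likelihood of a dataset under a benchmark problem
#'
#' Independent additive Gaussian noise per observable: the log-likelihood is
#' the sum over observables `i` and time points `k` of
#' `-log(sigma_i * sqrt(2*pi)) - (ytilde_ik - y_i(t_k))^2 / (2 * sigma_i^2)`.
#' Missing observations are skipped. A solver failure yields `-Inf`.
#'
#' @inheritParams log_prior
#' @param data a dataset tibble (columns `time`, `y1`, ...).
#' @return a scalar, possibly `-Inf`.
#' @export
log_likelihood <- function(problem, data, theta) {
  make_posterior(problem, data)$loglik(theta)
}

#' Log-posterior evaluation
#'
#' Returns the unnormalized log-posterior (log-likelihood plus log-prior)
#' together with its components and a solver-failure flag. Points outside
#' the prior box are rejected without invoking the ODE solver.
#'
#' @inheritParams log_likelihood
#' @return a list of class `posterior_eval` with fields `log_prior`,
#'   `log_likelihood`, `log_posterior`, `failed`.
#' @export
log_posterior <- function(problem, data, theta) {
  post <- make_posterior(problem, data)
  lpr <- post$lprior(theta)
  if (!is.finite(lpr))
    return(structure(list(log_prior = -Inf, log_likelihood = NA_real_,
                          log_posterior = -Inf, failed = FALSE),
                     class = "posterior_eval"))
  ll <- post$loglik(theta)
  structure(list(log_prior = lpr, log_likelihood = ll,
                 log_posterior = lpr + ll,
                 failed = is.infinite(ll) && post$last_failed()),
            class = "posterior_eval")
}

#' Tempered log-posterior
#'
#' The likelihood is raised to `1/beta` (`beta >= 1`), flattening the
#' posterior: `(1/beta) * log_likelihood + log_prior`. `beta = 1` recovers
#' the untempered log-posterior.
#'
#' @inheritParams log_likelihood
#' @param beta inverse-temperature exponent, `>= 1`.
#' @return a scalar, possibly `-Inf`.
#' @export
log_tempered_posterior <- function(problem, data, theta, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1)
    stop("beta must be a scalar >= 1")
  post <- make_posterior(problem, data)
  lpr <- post$lprior(theta)
  if (!is.finite(lpr)) return(-Inf)
  lpr + post$loglik(theta) / beta
}

# Build fast closures over (problem, data): repeated evaluation without
# re-deriving constants. This is the object the samplers drive.
# Returns an environment with lprior, loglik, lp, ll_lpr, simulate_y,
# grad_fim, counters.
make_posterior <- function(problem, data, rtol = 1e-8, atol = 1e-10) {
  m <- problem$model
  obs <- dataset_matrix(data)
  times <- data$time
  stopifnot(ncol(obs) == m$n_y, length(times) == nrow(obs))
  lower <- problem$theta_min
  upper <- problem$theta_max
  d <- n_par(problem)
  n_eta <- m$n_eta
  n_y <- m$n_y
  lg <- m$scale == "log10"
  n_per_obs <- unname(colSums(!is.na(obs)))
  env <- new.env(parent = emptyenv())
  env$n_eval <- 0L
  env$failed <- FALSE

  env$lprior <- function(theta) {
    if (all(theta >= lower) && all(theta <= upper)) 0 else -Inf
  }

  sim_y <- function(eta) {
    if (!is.null(m$solution)) return(m$solution(times, eta)$y)
    sim <- simulate_problem(problem,
                            theta = NULL_theta(problem, eta),
                            times = times, method = "numeric",
                            rtol = rtol, atol = atol)
    if (sim$failed) NULL else sim$y
  }

  # per-observable data columns and missingness masks, hoisted out of the
  # hot likelihood path
  obs_cols <- lapply(seq_len(n_y), function(i) obs[, i])
  na_masks <- lapply(obs_cols, function(v) is.na(v))
  any_na <- vapply(na_masks, any, TRUE)
  eta_idx <- seq_len(n_eta)
  sig_idx <- n_eta + seq_len(n_y)
  half_log2pi <- 0.5 * log(2 * pi)
  has_closed <- !is.null(m$solution)
  solfun <- m$solution

  env$loglik <- function(theta) {
    env$n_eval <- env$n_eval + 1L
    env$failed <- FALSE
    nat <- unname(theta)
    if (any(lg)) nat[lg] <- 10^nat[lg]
    sigma <- nat[sig_idx]
    if (any(sigma <= 0)) return(-Inf)
    y <- if (has_closed) solfun(times, nat[eta_idx])$y
         else sim_y(nat[eta_idx])
    if (is.null(y)) {
      env$failed <- TRUE
      return(-Inf)
    }
    ll <- 0
    for (i in seq_len(n_y)) {
      r <- obs_cols[[i]] - y[, i]
      if (any_na[i]) r <- r[!na_masks[[i]]]
      ll <- ll - n_per_obs[i] * (log(sigma[i]) + half_log2pi) -
        sum(r * r) / (2 * sigma[i]^2)
    }
    ll
  }

  env$lp <- function(theta) {
    if (any(theta < lower) || any(theta > upper)) return(-Inf)
    env$loglik(theta)
  }

  # c(loglik, logprior): the sampler-facing contract (tempering and swaps
  # need the likelihood separately).
  env$ll_lpr <- function(theta) {
    if (any(theta < lower) || any(theta > upper)) return(c(-Inf, -Inf))
    c(env$loglik(theta), 0)
  }

  env$last_failed <- function() env$failed
  env$grad_fim <- function(theta) posterior_grad_fim(problem, obs, times, theta,
                                                     rtol = rtol, atol = atol)
  env$lower <- lower
  env$upper <- upper
  env$d <- d
  env
}

# Rebuild a sampling-scale theta from natural eta (sigma slots unused by the
# simulation path).
NULL_theta <- function(problem, eta) {
  m <- problem$model
  th <- numeric(n_par(problem))
  lg <- m$scale == "log10"
  nat <- c(eta, rep(1, m$n_y))
  th <- nat
  th[lg] <- log10(pmax(nat[lg], .Machine$double.xmin))
  th
}

# ---- sensitivities ----------------------------------------------------------

# Observable sensitivities d y_i(t_k) / d eta_j (natural scale), as an
# n_t x n_y x n_eta array. Analytic when the model declares them, otherwise
# forward sensitivity ODEs (augmented system with finite-difference
# Jacobians of the vector field), with plain central differences of the
# solution as the last resort.
observable_sensitivities <- function(problem, times, eta,
                                     rtol = 1e-8, atol = 1e-10) {
  m <- problem$model
  if (!is.null(m$solution_sens)) return(m$solution_sens(times, eta))
  if (is.null(m$numeric_sim) && identical(m$observation, identity_obs))
    return(forward_sensitivities(problem, times, eta, rtol, atol))
  fd_sensitivities(problem, times, eta, rtol, atol)
}

# Forward sensitivity equations: augment the state with S = dx/deta and
# integrate jointly; Jacobians df/dx and df/deta by central differences of
# the RHS (cheap relative to the solve).
forward_sensitivities <- function(problem, times, eta, rtol, atol) {
  m <- problem$model
  n_x <- m$n_x; n_eta <- m$n_eta
  hstep <- function(v) pmax(abs(v), 1) * 1e-6

  jac_x <- function(x, t) {
    h <- hstep(x)
    J <- matrix(0, n_x, n_x)
    for (j in seq_len(n_x)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      xm <- x; xm[j] <- xm[j] - h[j]
      J[, j] <- (m$rhs(xp, t, eta) - m$rhs(xm, t, eta)) / (2 * h[j])
    }
    J
  }
  jac_eta <- function(x, t) {
    h <- hstep(eta)
    J <- matrix(0, n_x, n_eta)
    for (j in seq_len(n_eta)) {
      ep <- eta; ep[j] <- ep[j] + h[j]
      em <- eta; em[j] <- em[j] - h[j]
      J[, j] <- (m$rhs(x, t, ep) - m$rhs(x, t, em)) / (2 * h[j])
    }
    J
  }
  # dx0/deta by central differences of the initial-state map.
  h0 <- hstep(eta)
  S0 <- matrix(0, n_x, n_eta)
  for (j in seq_len(n_eta)) {
    ep <- eta; ep[j] <- ep[j] + h0[j]
    em <- eta; em[j] <- em[j] - h0[j]
    S0[, j] <- (m$initial_state(ep) - m$initial_state(em)) / (2 * h0[j])
  }

  aug_rhs <- function(t, z, p) {
    x <- z[seq_len(n_x)]
    S <- matrix(z[-seq_len(n_x)], n_x, n_eta)
    Jx <- jac_x(x, t)
    list(c(m$rhs(x, t, eta), as.vector(Jx %*% S + jac_eta(x, t))))
  }
  t_start <- min(problem$t_interval[1], times[1])
  tt <- unique(c(t_start, times))
  z0 <- c(m$initial_state(eta), as.vector(S0))
  sol <- tryCatch(
    suppressWarnings(deSolve::lsoda(z0, tt, aug_rhs, parms = NULL,
                                    rtol = rtol, atol = atol)),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) != length(tt) || !all(is.finite(sol[, -1])))
    stop("forward sensitivity integration failed")
  rows <- match(times, sol[, 1])
  # identity observation: observable sensitivities are state sensitivities
  s <- array(0, dim = c(length(times), m$n_y, n_eta))
  for (j in seq_len(n_eta)) {
    cols <- 1 + n_x + (j - 1) * n_x + seq_len(n_x)
    s[, , j] <- sol[rows, cols, drop = FALSE][, seq_len(m$n_y), drop = FALSE]
  }
  s
}

# Central finite differences of the simulated observables (fallback route).
fd_sensitivities <- function(problem, times, eta, rtol, atol) {
  m <- problem$model
  n_eta <- m$n_eta
  s <- array(0, dim = c(length(times), m$n_y, n_eta))
  h <- pmax(abs(eta), 1e-3) * 1e-6
  sim1 <- function(e) {
    out <- if (!is.null(m$solution)) m$solution(times, e)$y
    else if (!is.null(m$numeric_sim)) m$numeric_sim(times, e, rtol, atol)$y
    else {
      r <- simulate_problem(problem, NULL_theta(problem, e), times,
                            method = "numeric", rtol = rtol, atol = atol)
      if (r$failed) stop("simulation failed in finite differences")
      r$y
    }
    out
  }
  for (j in seq_len(n_eta)) {
    ep <- eta; ep[j] <- ep[j] + h[j]
    em <- eta; em[j] <- em[j] - h[j]
    s[, , j] <- (sim1(ep) - sim1(em)) / (2 * h[j])
  }
  s
}

posterior_grad_fim <- function(problem, obs, times, theta,
                               rtol = 1e-8, atol = 1e-10,
                               reg_lambda = 1e-8, cond_max = 1e12) {
  m <- problem$model
  d <- n_par(problem)
  n_eta <- m$n_eta; n_y <- m$n_y
  lg <- m$scale == "log10"
  nat <- theta; nat[lg] <- 10^nat[lg]
  eta <- nat[seq_len(n_eta)]
  sigma <- nat[n_eta + seq_len(n_y)]

  sim <- if (!is.null(m$solution)) m$solution(times, eta)$y else {
    r <- simulate_problem(problem, NULL_theta(problem, eta), times,
                          method = "numeric", rtol = rtol, atol = atol)
    if (r$failed) stop("solver failure in sensitivity computation")
    r$y
  }
  s <- observable_sensitivities(problem, times, eta, rtol, atol)

  grad_nat <- numeric(d)
  fim_nat <- matrix(0, d, d)
  for (i in seq_len(n_y)) {
    r_i <- obs[, i] - sim[, i]
    keep <- !is.na(r_i)
    r_i <- r_i[keep]
    S_i <- matrix(s[keep, i, ], ncol = n_eta)
    grad_nat[seq_len(n_eta)] <- grad_nat[seq_len(n_eta)] +
      as.numeric(crossprod(S_i, r_i)) / sigma[i]^2
    grad_nat[n_eta + i] <- sum(r_i^2) / sigma[i]^3 - length(r_i) / sigma[i]
    fim_nat[seq_len(n_eta), seq_len(n_eta)] <-
      fim_nat[seq_len(n_eta), seq_len(n_eta)] + crossprod(S_i) / sigma[i]^2
    fim_nat[n_eta + i, n_eta + i] <- 2 * length(r_i) / sigma[i]^2
  }

  # chain rule to the sampling scale: d/dtheta = d/dnat * nat * ln(10)
  jac <- rep(1, d)
  jac[lg] <- nat[lg] * log(10)
  grad <- grad_nat * jac
  fim <- fim_nat * outer(jac, jac)
  fim <- (fim + t(fim)) / 2

  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  cond_flag <- (min(ev) <= 0) || (max(ev) / max(min(ev), .Machine$double.xmin) > cond_max)
  lam <- reg_lambda * max(diag(fim), .Machine$double.eps)
  fim_reg <- fim + diag(lam, d)
  list(gradient = grad, fim = fim_reg, fim_raw = fim, ill_conditioned = cond_flag)
}

#' Gradient and Fisher information of the log-posterior
#'
#' Computes the gradient of the unnormalized log-posterior with respect to
#' the sampling-scale parameters (chain-ruled through the log10
#' reparameterization where applicable) and the expected Fisher information
#' for the Gaussian noise model: the dynamic block is
#' `sum_{i,k} s_ik s_ik' / sigma_i^2` with observable sensitivities
#' `s_ik = d y_i(t_k) / d eta`, the noise block is `diag(2 n_i / sigma_i^2)`,
#' and cross terms vanish. The returned matrix is symmetrized and
#' regularized by `lambda * I` with `lambda = 1e-8 * max(diag)`.
#'
#' Sensitivities come from the model's analytic solution when declared and
#' from forward sensitivity equations (augmented ODE system) otherwise.
#'
#' @inheritParams log_likelihood
#' @return `list(gradient, fim, fim_raw, ill_conditioned)`.
#' @export
sensitivities <- function(problem, data, theta) {
  stopifnot(length(theta) == n_par(problem))
  if (!is.finite(log_prior(problem, theta)))
    stop("theta must lie inside the prior box")
  posterior_grad_fim(problem, dataset_matrix(data), data$time, theta)
}
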