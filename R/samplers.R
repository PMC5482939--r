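# Metropolis-Hastings kernel and the five sampler variants: adaptive
# Metropolis with dimension- or acceptance-rate-based proposal scaling
# (AM(dim), AM(acc)), delayed rejection adaptive Metropolis (DRAM), the
# Metropolis-adjusted Langevin algorithm (MALA), parallel tempering (PT)
# and parallel hierarchical sampling (PHS).

#' Sampler control settings
#'
#' Tuning parameters shared by [run_sampler()]. Defaults follow common
#' adaptive-MCMC practice: acceptance-rate adaptation targets 0.234 with a
#' stochastic-approximation step decaying as `i^-0.51` (diminishing
#' adaptation), covariance adaptation starts after 100 iterations with an
#' `eps * I` proposal before, and `eps = 1e-8 * mean(prior range)^2`.
#'
#' @param scheme proposal-scaling scheme, `"acc"` (acceptance-rate-based) or
#'   `"dim"` (dimension-based, factor `2.38^2/d`).
#' @param target_acceptance adaptation target for `"acc"`; default 0.234
#'   (0.574 for MALA's step size).
#' @param adapt_start iteration at which covariance adaptation begins.
#' @param decay exponent of the adaptation step `i^-decay`; must lie in
#'   (0.5, 1] so that adaptation diminishes.
#' @param eps covariance regularization; `NULL` means
#'   `1e-8 * mean(upper - lower)^2`.
#' @param sigma0 initial proposal covariance matrix; `NULL` means `eps * I`.
#' @param dram_tries total proposal stages for DRAM (>= 1).
#' @param dram_scale per-stage proposal down-scaling factor (stage covariance
#'   is divided by `dram_scale^2` per extra stage).
#' @param mala_step initial MALA step size (adapted toward
#'   `target_acceptance`).
#' @param n_temps initial number of tempered chains L0 for PT.
#' @param beta_max hottest initial inverse-temperature exponent (initial
#'   ladder is geometric from 1 to `beta_max`).
#' @param swap_strategy `"aa"` (all adjacent pairs) or `"ee"` (the pair with
#'   the most similar log-likelihood).
#' @param swap_target target swap-acceptance rate for temperature-spacing
#'   adaptation.
#' @param adaptive_temps if `TRUE`, the hottest chain is removed when the
#'   hottest adjacent log-spacing collapses below `spacing_threshold`
#'   (`L` never drops below 2); the default is a fixed ladder.
#' @param spacing_threshold log-beta spacing below which the hottest chain
#'   is removed under `adaptive_temps`.
#' @param pt_inner within-temperature kernel for PT: `"am"` (AM(acc)) or
#'   `"mala"`.
#' @param n_aux number of PHS auxiliary chains.
#' @return a list of class `sampler_control`.
#' @export
sampler_control <- function(scheme = c("acc", "dim"), target_acceptance = NULL,
                            adapt_start = 100, decay = 0.51, eps = NULL,
                            sigma0 = NULL, dram_tries = 2, dram_scale = 5,
                            mala_step = 1, n_temps = 10, beta_max = 1e4,
                            swap_strategy = c("aa", "ee"), swap_target = 0.23,
                            adaptive_temps = FALSE, spacing_threshold = 0.01,
                            pt_inner = c("am", "mala"), n_aux = 4) {
  stopifnot(decay > 0.5, decay <= 1, dram_tries >= 1, n_temps >= 1, n_aux >= 1)
  structure(list(scheme = match.arg(scheme),
                 target_acceptance = target_acceptance,
                 adapt_start = adapt_start, decay = decay, eps = eps,
                 sigma0 = sigma0, dram_tries = dram_tries,
                 dram_scale = dram_scale, mala_step = mala_step,
                 n_temps = n_temps, beta_max = beta_max,
                 swap_strategy = match.arg(swap_strategy),
                 swap_target = swap_target, adaptive_temps = adaptive_temps,
                 spacing_threshold = spacing_threshold,
                 pt_inner = match.arg(pt_inner), n_aux = n_aux),
            class = "sampler_control")
}

#' Custom sampling target
#'
#' Wraps an arbitrary log-likelihood on a box support into the target
#' contract used by [run_sampler()], for sampling distributions that are not
#' ODE posteriors (toy targets, test fixtures). The prior is uniform on
#' `[lower, upper]` with the constant dropped.
#'
#' @param log_likelihood `function(theta)` returning a scalar log-density
#'   (up to a constant).
#' @param lower,upper box bounds.
#' @param gradient,fim optional `function(theta)` returning the gradient and
#'   the metric matrix; required by MALA.
#' @param name label.
#' @return a target object usable as the first argument of [run_sampler()].
#' @export
custom_target <- function(log_likelihood, lower, upper,
                          gradient = NULL, fim = NULL, name = "custom") {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  env <- new.env(parent = emptyenv())
  env$d <- d; env$lower <- lower; env$upper <- upper
  env$name <- name
  env$n_eval <- 0L
  env$lprior <- function(theta)
    if (all(theta >= lower) && all(theta <= upper)) 0 else -Inf
  env$loglik <- function(theta) {
    env$n_eval <- env$n_eval + 1L
    log_likelihood(theta)
  }
  env$lp <- function(theta) {
    lpr <- env$lprior(theta)
    if (!is.finite(lpr)) return(-Inf)
    lpr + env$loglik(theta)
  }
  env$ll_lpr <- function(theta) {
    lpr <- env$lprior(theta)
    if (!is.finite(lpr)) return(c(-Inf, -Inf))
    c(env$loglik(theta), lpr)
  }
  env$grad_fim <- if (is.null(gradient) || is.null(fim)) NULL else
    function(theta) list(gradient = gradient(theta), fim = fim(theta))
  class(env) <- "mcmc_target"
  env
}

as_target <- function(x, data = NULL) {
  if (inherits(x, "mcmc_target")) return(x)
  if (inherits(x, "benchmark_problem")) {
    if (is.null(data)) stop("a dataset is required for a benchmark problem")
    t <- make_posterior(x, data)
    t$name <- x$model$name
    return(t)
  }
  if (is.environment(x) && !is.null(x$ll_lpr)) return(x)
  stop("cannot interpret target of class ", paste(class(x), collapse = "/"))
}

# ---- Metropolis-Hastings kernel --------------------------------------------

#' One Metropolis-Hastings step
#'
#' Symmetric proposals are accepted with probability
#' `min(1, exp(log_target(prop) - log_target(current)))`; asymmetric
#' proposals supply `log_q_forward`/`log_q_reverse` and the ratio includes
#' the proposal-density correction. A rejected proposal leaves `theta`
#' unchanged. A target returning `NaN` is treated as `-Inf` with a warning.
#'
#' @param state `list(theta, log_target)`.
#' @param target `function(theta)` returning the log-target density.
#' @param proposal_sampler `function(theta)` returning either a proposal
#'   vector or `list(theta, log_q_forward, log_q_reverse)`.
#' @return `list(state = <updated state>, accepted = <logical>)`.
#' @export
mh_step <- function(state, target, proposal_sampler) {
  prop <- proposal_sampler(state$theta)
  if (!is.list(prop)) prop <- list(theta = prop, log_q_forward = 0, log_q_reverse = 0)
  lt <- target(prop$theta)
  if (is.nan(lt)) {
    warning("target returned NaN; treating as -Inf")
    lt <- -Inf
  }
  log_alpha <- (lt - state$log_target) +
    (prop$log_q_reverse %||% 0) - (prop$log_q_forward %||% 0)
  accepted <- is.finite(lt) && log(stats::runif(1)) < log_alpha
  if (accepted) state <- list(theta = prop$theta, log_target = lt)
  list(state = state, accepted = accepted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- adaptive-Metropolis proposal state ------------------------------------

#' Adaptive proposal state
#'
#' Holds the running mean, scatter matrix and scaling state of an adaptive
#' Metropolis proposal. [am_update()] advances it by one sample.
#'
#' @param d parameter dimension.
#' @param eps covariance regularization added as `eps * I`.
#' @param scheme `"dim"` (proposal covariance `(2.38^2/d) * Sigma + eps*I`)
#'   or `"acc"` (a scalar log-scale adapted toward `target_acceptance`
#'   multiplies `Sigma + eps*I`).
#' @param target_acceptance acceptance-rate target for `"acc"`.
#' @param adapt_start iteration at which the empirical covariance takes over
#'   from `sigma0`.
#' @param decay adaptation-step decay exponent.
#' @param sigma0 initial proposal covariance (default `eps * I`).
#' @return a list of class `proposal_state` with element `covariance`
#'   holding the current proposal covariance.
#' @export
proposal_state <- function(d, eps = 1e-8, scheme = c("dim", "acc"),
                           target_acceptance = 0.234, adapt_start = 100,
                           decay = 0.51, sigma0 = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(sigma0)) sigma0 <- diag(eps, d)
  structure(list(d = d, mean = numeric(d), M2 = matrix(0, d, d),
                 iteration = 0L, acceptance_count = 0L, logscale = 0,
                 eps = eps, scheme = scheme,
                 target_acceptance = target_acceptance,
                 adapt_start = adapt_start, decay = decay,
                 covariance = sigma0),
            class = "proposal_state")
}

#' Advance an adaptive proposal by one sample
#'
#' Updates the running mean and scatter by the rank-1 recursion (so that the
#' recursive covariance equals the batch covariance of the same samples) and
#' recomputes the proposal covariance according to the scaling scheme. With
#' a degenerate history (zero empirical covariance) the proposal falls back
#' to `eps * I`.
#'
#' @param proposal a [proposal_state()].
#' @param new_sample the chain state after the current MH step.
#' @param accepted whether the step was accepted (drives `"acc"` scaling).
#' @return the updated `proposal_state`.
#' @export
am_update <- function(proposal, new_sample, accepted = TRUE) {
  p <- proposal
  i <- p$iteration + 1L
  delta <- new_sample - p$mean
  p$mean <- p$mean + delta / i
  p$M2 <- p$M2 + tcrossprod(delta, new_sample - p$mean)
  p$iteration <- i
  p$acceptance_count <- p$acceptance_count + as.integer(accepted)
  if (p$scheme == "acc")
    p$logscale <- min(30, max(-30, p$logscale +
      i^(-p$decay) * (as.numeric(accepted) - p$target_acceptance)))
  if (i > p$adapt_start) {
    sig <- p$M2 / (i - 1)
    sig <- (sig + t(sig)) / 2
    p$covariance <- if (p$scheme == "dim")
      (2.38^2 / p$d) * sig + diag(p$eps, p$d)
    else exp(p$logscale) * (sig + diag(p$eps, p$d))
  }
  p
}

#' Empirical covariance held by a proposal state
#'
#' @param proposal a [proposal_state()].
#' @return the running sample covariance matrix.
#' @export
proposal_empirical_cov <- function(proposal) {
  if (proposal$iteration < 2) return(matrix(0, proposal$d, proposal$d))
  s <- proposal$M2 / (proposal$iteration - 1)
  (s + t(s)) / 2
}

# ---- internal chain machinery ----------------------------------------------

# Chains are environments for in-place mutation in the hot loop; the math is
# identical to the proposal_state recursion above.
new_chain <- function(theta, llpr, beta, d, ctl) {
  e <- new.env(parent = emptyenv())
  e$theta <- theta
  e$ll <- llpr[1]; e$lpr <- llpr[2]
  e$beta <- beta
  e$lt <- if (is.finite(llpr[2])) llpr[1] / beta + llpr[2] else -Inf
  e$mean <- numeric(d); e$M2 <- matrix(0, d, d)
  e$iter <- 0L; e$nacc <- 0L
  e$logscale <- 0
  e$cholP <- chol(ctl$sigma0)
  e$logeps <- log(ctl$mala_step)
  e$gf <- NULL
  e
}

chain_adapt <- function(e, ctl, d, accepted) {
  i <- e$iter + 1L
  e$iter <- i
  delta <- e$theta - e$mean
  e$mean <- e$mean + delta / i
  e$M2 <- e$M2 + tcrossprod(delta, e$theta - e$mean)
  if (accepted) e$nacc <- e$nacc + 1L
  if (ctl$acc_scheme)
    e$logscale <- min(30, max(-30, e$logscale +
      i^(-ctl$decay) * ((if (accepted) 1 else 0) - ctl$acc_target)))
  # the covariance Cholesky is refreshed every few iterations: the scalar
  # acc-scale is applied at draw time, so only the shape factor is cached
  if (i > ctl$adapt_start && i %% ctl$chol_every == 0L) {
    sig <- e$M2 / (i - 1)
    P <- (sig + t(sig)) / 2 + ctl$epsI
    if (!ctl$acc_scheme) P <- ctl$sd_factor * P +
      (1 - ctl$sd_factor) * ctl$epsI # dim: sd_factor * Sigma + eps*I
    R <- tryCatch(chol(P), error = function(err) NULL)
    if (!is.null(R)) e$cholP <- R
  }
  invisible(e)
}

# One random-walk Metropolis step with AM adaptation on a (tempered)
# target. The adaptation bookkeeping is inlined (this is the hot loop).
step_rw <- function(e, ll_lpr, ctl, d) {
  i <- e$iter + 1L
  z <- stats::rnorm(d)
  step <- drop(crossprod(e$cholP, z))
  if (ctl$acc_scheme && i > ctl$adapt_start)
    step <- step * exp(e$logscale / 2)
  prop <- e$theta + step
  u <- log(stats::runif(1))
  v <- ll_lpr(prop)
  ltp <- if (is.finite(v[2])) v[1] / e$beta + v[2] else -Inf
  if (is.nan(ltp)) {
    warning("log-target returned NaN; treating as -Inf")
    ltp <- -Inf
  }
  accepted <- is.finite(ltp) && (ltp - e$lt > u)
  if (accepted) {
    e$theta <- prop; e$ll <- v[1]; e$lpr <- v[2]; e$lt <- ltp
    e$nacc <- e$nacc + 1L
  }
  e$iter <- i
  th <- e$theta
  delta <- th - e$mean
  e$mean <- mu <- e$mean + delta / i
  e$M2 <- e$M2 + tcrossprod(delta, th - mu)
  if (ctl$acc_scheme)
    e$logscale <- min(30, max(-30, e$logscale +
      i^(-ctl$decay) * ((if (accepted) 1 else 0) - ctl$acc_target)))
  if (i > ctl$adapt_start && i %% ctl$chol_every == 0L) {
    sig <- e$M2 / (i - 1)
    P <- (sig + t(sig)) / 2 + ctl$epsI
    if (!ctl$acc_scheme) P <- ctl$sd_factor * P +
      (1 - ctl$sd_factor) * ctl$epsI
    R <- tryCatch(chol(P), error = function(err) NULL)
    if (!is.null(R)) e$cholP <- R
  }
  accepted
}

# Log proposal density (up to a constant) of N(center, Sigma) with
# chol(Sigma) = R, evaluated at x.
log_q_gauss <- function(x, center, R) {
  w <- forwardsolve(t(R), x - center)
  -0.5 * sum(w * w)
}

# ---- DRAM -------------------------------------------------------------------

#' One delayed-rejection step
#'
#' First proposes from the current adaptive proposal; on rejection, retries
#' from a down-scaled proposal and accepts with the delayed-rejection
#' probability
#' `alpha2 = min(1, pi(y2) q(y2 -> y1) (1 - alpha1(y2, y1)) /
#'               (pi(x) q(x -> y1) (1 - alpha1(x, y1))))`,
#' which preserves reversibility. Up to `n_tries` total stages are used,
#' each down-scaling the proposal standard deviation by a further factor
#' `scale`.
#'
#' @param state `list(theta, log_target)`.
#' @param target `function(theta)` returning the log-target density.
#' @param chol_prop upper-triangular Cholesky factor of the stage-1 proposal
#'   covariance.
#' @param n_tries maximum number of stages (>= 1).
#' @param scale per-stage standard-deviation down-scaling (default 5, i.e.
#'   covariance divided by 25 at stage 2).
#' @return `list(state, accepted, stages_used)`.
#' @export
dram_step <- function(state, target, chol_prop, n_tries = 2, scale = 5) {
  d <- length(state$theta)
  lt_x <- state$log_target
  eval_lt <- function(th) {
    v <- target(th)
    if (is.nan(v)) {
      warning("target returned NaN; treating as -Inf")
      v <- -Inf
    }
    v
  }
  # stage 1
  R1 <- chol_prop
  y1 <- state$theta + drop(crossprod(R1, stats::rnorm(d)))
  lt_y1 <- eval_lt(y1)
  la1_x_y1 <- min(0, lt_y1 - lt_x)
  if (is.finite(lt_y1) && log(stats::runif(1)) < la1_x_y1)
    return(list(state = list(theta = y1, log_target = lt_y1),
                accepted = TRUE, stages_used = 1L))
  if (n_tries < 2)
    return(list(state = state, accepted = FALSE, stages_used = 1L))

  stage <- 1L
  repeat {
    stage <- stage + 1L
    Rk <- R1 / scale^(stage - 1)
    y2 <- state$theta + drop(crossprod(Rk, stats::rnorm(d)))
    lt_y2 <- eval_lt(y2)
    if (is.finite(lt_y2)) {
      la1_y2_y1 <- min(0, lt_y1 - lt_y2)
      log_num <- lt_y2 + log_q_gauss(y1, y2, R1) + log1mexp(la1_y2_y1)
      log_den <- lt_x + log_q_gauss(y1, state$theta, R1) + log1mexp(la1_x_y1)
      if (log(stats::runif(1)) < log_num - log_den)
        return(list(state = list(theta = y2, log_target = lt_y2),
                    accepted = TRUE, stages_used = stage))
    } else {
      stats::runif(1) # keep the draw schedule aligned
    }
    if (stage >= n_tries)
      return(list(state = state, accepted = FALSE, stages_used = stage))
  }
}

# log(1 - exp(x)) for x <= 0, stable near 0 and -Inf.
log1mexp <- function(x) {
  if (x >= 0) return(-Inf)
  if (x > -log(2)) log(-expm1(x)) else log1p(-exp(x))
}

# ---- MALA -------------------------------------------------------------------

#' One Metropolis-adjusted Langevin step
#'
#' Preconditioned Langevin proposal: mean
#' `theta + (eps^2 / 2) * G^-1 grad`, covariance `eps^2 * G^-1`, where `G`
#' is the (regularized) Fisher information at the current point. Acceptance
#' uses the full asymmetric MH ratio with the proposal densities evaluated
#' at both endpoints (the reverse move uses gradient and metric at the
#' proposal). A solver failure at the proposal rejects the move.
#'
#' @param state `list(theta, log_target, grad, fim)`; `grad`/`fim` may be
#'   `NULL` and are then computed.
#' @param target `function(theta)` returning
#'   `list(lp, gradient, fim)` (with `lp = -Inf` allowed; gradient/fim may
#'   then be `NULL`).
#' @param step_size the Langevin step size `eps`.
#' @return `list(state, accepted)`; the returned state caches gradient and
#'   metric for reuse.
#' @export
mala_step <- function(state, target, step_size) {
  d <- length(state$theta)
  if (is.null(state$grad) || is.null(state$fim)) {
    cur <- target(state$theta)
    state$log_target <- cur$lp
    state$grad <- cur$gradient
    state$fim <- cur$fim
  }
  R <- chol(state$fim)
  drift <- backsolve(R, forwardsolve(t(R), state$grad))
  mu_fwd <- state$theta + step_size^2 / 2 * drift
  z <- stats::rnorm(d)
  prop <- mu_fwd + step_size * backsolve(R, z)
  u <- log(stats::runif(1))

  cand <- target(prop)
  if (!is.finite(cand$lp) || is.null(cand$gradient) || is.null(cand$fim))
    return(list(state = state, accepted = FALSE))
  Rp <- chol(cand$fim)
  drift_p <- backsolve(Rp, forwardsolve(t(Rp), cand$gradient))
  mu_rev <- prop + step_size^2 / 2 * drift_p

  log_q <- function(x, mu, Rm) {
    # N(mu, step^2 * G^-1): log density up to a shared constant
    v <- drop(Rm %*% (x - mu)) / step_size
    sum(log(diag(Rm))) - 0.5 * sum(v * v)
  }
  log_alpha <- (cand$lp - state$log_target) +
    log_q(state$theta, mu_rev, Rp) - log_q(prop, mu_fwd, R)
  if (is.nan(log_alpha)) log_alpha <- -Inf
  if (u < log_alpha) {
    state <- list(theta = prop, log_target = cand$lp,
                  grad = cand$gradient, fim = cand$fim)
    list(state = state, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

# ---- parallel tempering -----------------------------------------------------

#' Swap acceptance probability between two tempered chains
#'
#' `min(1, exp((1/beta_l - 1/beta_m) * (ll_m - ll_l)))`.
#'
#' @param beta_l,beta_m inverse-temperature exponents of the two levels.
#' @param ll_l,ll_m current log-likelihoods of the two levels.
#' @return the acceptance probability.
#' @export
pt_swap_probability <- function(beta_l, beta_m, ll_l, ll_m) {
  min(1, exp((1 / beta_l - 1 / beta_m) * (ll_m - ll_l)))
}

#' Equi-energy pair proposal
#'
#' Returns the index pair of chains whose current log-likelihoods (energies)
#' are most similar; ties resolve to the first such pair.
#'
#' @param ll vector of per-chain log-likelihoods.
#' @return integer vector of length 2.
#' @export
pt_propose_ee <- function(ll) {
  L <- length(ll)
  stopifnot(L >= 2)
  best <- c(1L, 2L); bestd <- Inf
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    dd <- abs(ll[i] - ll[j])
    if (dd < bestd) { bestd <- dd; best <- c(i, j) }
  }
  best
}

#' Propose and apply temperature swaps
#'
#' Under `"aa"` every adjacent pair is proposed for a swap in sequence;
#' under `"ee"` the single pair with the most similar log-likelihood is
#' proposed. A swap of levels `l` and `m` is accepted with probability
#' [pt_swap_probability()]; accepted swaps exchange the chain states and the
#' cached tempered values are re-derived. With fewer than 2 chains this is a
#' no-op.
#'
#' @param states a list of chain states, each `list(theta, ll, lpr)`.
#' @param betas inverse-temperature exponents aligned with `states`.
#' @param strategy `"aa"` or `"ee"`.
#' @return `list(states, proposed, accepted)` where `proposed`/`accepted`
#'   are matrices with one row per proposed pair.
#' @export
pt_swap <- function(states, betas, strategy = c("aa", "ee")) {
  strategy <- match.arg(strategy)
  L <- length(states)
  if (L < 2)
    return(list(states = states, proposed = integer(0), accepted = logical(0)))
  pairs <- if (strategy == "aa")
    lapply(seq_len(L - 1), function(l) c(l, l + 1L))
  else list(pt_propose_ee(vapply(states, `[[`, 0, "ll")))
  acc <- logical(length(pairs))
  for (k in seq_along(pairs)) {
    l <- pairs[[k]][1]; m <- pairs[[k]][2]
    a <- pt_swap_probability(betas[l], betas[m], states[[l]]$ll, states[[m]]$ll)
    if (stats::runif(1) < a) {
      tmp <- states[[l]]; states[[l]] <- states[[m]]; states[[m]] <- tmp
      acc[k] <- TRUE
    }
  }
  list(states = states,
       proposed = do.call(rbind, pairs), accepted = acc)
}

# Initial geometric temperature ladder: beta_1 = 1, beta_L = beta_max.
init_ladder <- function(L, beta_max) {
  if (L == 1) return(1)
  exp(seq(0, log(beta_max), length.out = L))
}

# ---- run driver -------------------------------------------------------------

#' Run an MCMC sampler
#'
#' Executes `n_iter` iterations of the requested algorithm on the posterior
#' of a benchmark problem (or a [custom_target()]), recording the trace of
#' the main/untempered chain, its unnormalized log-posterior, acceptance
#' statistics and CPU seconds. A run is fully reproducible from
#' `(algorithm, control, init, seed)`.
#'
#' Algorithms: `"am"` (adaptive Metropolis; scheme `"acc"` or `"dim"`),
#' `"dram"` (delayed rejection, `"dim"` scaling only), `"mala"`
#' (Fisher-preconditioned Langevin), `"pt"` (parallel tempering with
#' AM(acc) or MALA within each tempered chain, adjacent or equi-energy
#' swaps, stochastic-approximation temperature-spacing adaptation, optional
#' adaptive chain count), `"phs"` (parallel hierarchical sampling: auxiliary
#' AM(acc) chains on the posterior, the main chain exchanging with a random
#' auxiliary every iteration, unconditionally).
#'
#' With `n_temps = 1`, PT degenerates exactly to AM(acc): the trace is
#' identical to an `"am"` run under the same seed.
#'
#' @param problem a [benchmark_problem()] or [custom_target()].
#' @param data dataset tibble (required for benchmark problems).
#' @param algorithm one of `"am"`, `"dram"`, `"mala"`, `"pt"`, `"phs"`.
#' @param n_iter number of iterations.
#' @param init initial point (vector), or a matrix with one row per chain
#'   for multi-chain algorithms; `NULL` draws from the prior.
#' @param seed RNG seed for the run.
#' @param control a [sampler_control()].
#' @param scenario optional scenario label stored in the result.
#' @param extra_cpu_seconds CPU time to attribute to the run on top of the
#'   sampling loop (e.g. multi-start initialization cost).
#' @return an object of class `sampler_run` with elements `trace`
#'   (`n_iter x d`), `log_posterior`, `acceptance_rate`, `cpu_seconds`,
#'   `algorithm`, `settings`, `seed`, `problem`, `scenario`, and for PT the
#'   final `ladder` and `swap_rate`; for PHS `swap_acceptance_count`.
#' @export
run_sampler <- function(problem, data = NULL,
                        algorithm = c("am", "dram", "mala", "pt", "phs"),
                        n_iter, init = NULL, seed = NULL,
                        control = sampler_control(), scenario = NULL,
                        extra_cpu_seconds = 0) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_iter >= 1)
  target <- as_target(problem, data)
  d <- target$d
  lower <- target$lower; upper <- target$upper

  ctl <- unclass(control)
  if (algorithm == "dram" && ctl$scheme != "dim")
    stop("DRAM supports only the 'dim' adaptation scheme")
  if (is.null(ctl$eps)) ctl$eps <- 1e-8 * mean(upper - lower)^2
  if (is.null(ctl$sigma0)) ctl$sigma0 <- diag(ctl$eps, d)
  ctl$sd_factor <- 2.38^2 / d
  ctl$acc_target <- ctl$target_acceptance %||%
    (if (algorithm == "mala") 0.574 else 0.234)
  if (algorithm %in% c("pt", "phs")) ctl$scheme <- "acc"
  ctl$acc_scheme <- ctl$scheme == "acc"
  ctl$epsI <- diag(ctl$eps, d)
  ctl$chol_every <- 25L

  if (!is.null(seed)) set.seed(seed)

  n_chains <- switch(algorithm, pt = ctl$n_temps, phs = ctl$n_aux + 1L, 1L)
  if (is.null(init)) {
    init <- matrix(stats::runif(n_chains * d, rep(lower, each = n_chains),
                                rep(upper, each = n_chains)),
                   nrow = n_chains)
  } else {
    init <- if (is.matrix(init)) init else matrix(init, nrow = 1)
    if (nrow(init) < n_chains)
      init <- init[rep_len(seq_len(nrow(init)), n_chains), , drop = FALSE]
  }
  stopifnot(ncol(init) == d)

  trace <- matrix(NA_real_, n_iter, d)
  colnames(trace) <- names(lower) %||% paste0("theta", seq_len(d))
  lp_trace <- numeric(n_iter)

  t0 <- proc.time()
  res <- switch(algorithm,
    am = run_single_am(target, init[1, ], n_iter, ctl, d, trace, lp_trace),
    dram = run_single_dram(target, init[1, ], n_iter, ctl, d, trace, lp_trace),
    mala = run_single_mala(target, init[1, ], n_iter, ctl, d, trace, lp_trace),
    pt = run_pt(target, init, n_iter, ctl, d, trace, lp_trace),
    phs = run_phs(target, init, n_iter, ctl, d, trace, lp_trace))
  dt <- proc.time() - t0
  cpu <- sum(dt[c("user.self", "sys.self")], na.rm = TRUE) + extra_cpu_seconds

  structure(c(res,
              list(cpu_seconds = cpu, algorithm = algorithm,
                   settings = control, seed = seed,
                   problem = target$name %||% "custom",
                   scenario = scenario %||% algorithm,
                   n_iter = as.integer(n_iter),
                   n_eval = target$n_eval)),
            class = "sampler_run")
}

run_single_am <- function(target, theta0, n_iter, ctl, d, trace, lp_trace) {
  llpr <- target$ll_lpr(theta0)
  if (!is.finite(llpr[2])) stop("initial point lies outside the prior box")
  ch <- new_chain(theta0, llpr, 1, d, ctl)
  ll_lpr <- target$ll_lpr
  for (i in seq_len(n_iter)) {
    step_rw(ch, ll_lpr, ctl, d)
    trace[i, ] <- ch$theta
    lp_trace[i] <- ch$ll + ch$lpr
  }
  list(trace = trace, log_posterior = lp_trace,
       acceptance_rate = ch$nacc / n_iter)
}

run_single_dram <- function(target, theta0, n_iter, ctl, d, trace, lp_trace) {
  llpr <- target$ll_lpr(theta0)
  if (!is.finite(llpr[2])) stop("initial point lies outside the prior box")
  ch <- new_chain(theta0, llpr, 1, d, ctl)
  lp_fun <- function(th) {
    v <- target$ll_lpr(th)
    if (is.finite(v[2])) v[1] + v[2] else -Inf
  }
  state <- list(theta = ch$theta, log_target = llpr[1] + llpr[2])
  for (i in seq_len(n_iter)) {
    out <- dram_step(state, lp_fun, ch$cholP,
                     n_tries = ctl$dram_tries, scale = ctl$dram_scale)
    state <- out$state
    ch$theta <- state$theta
    ch$lt <- state$log_target
    chain_adapt(ch, ctl, d, out$accepted)
    trace[i, ] <- state$theta
    lp_trace[i] <- state$log_target
  }
  list(trace = trace, log_posterior = lp_trace,
       acceptance_rate = ch$nacc / n_iter)
}

run_single_mala <- function(target, theta0, n_iter, ctl, d, trace, lp_trace) {
  if (is.null(target$grad_fim))
    stop("MALA requires gradient and Fisher information for this target")
  tfun <- function(th) {
    v <- target$ll_lpr(th)
    if (!is.finite(v[2])) return(list(lp = -Inf, gradient = NULL, fim = NULL))
    lp <- v[1] + v[2]
    if (!is.finite(lp)) return(list(lp = -Inf, gradient = NULL, fim = NULL))
    gf <- tryCatch(target$grad_fim(th), error = function(e) NULL)
    if (is.null(gf)) return(list(lp = -Inf, gradient = NULL, fim = NULL))
    list(lp = lp, gradient = gf$gradient, fim = gf$fim)
  }
  cur <- tfun(theta0)
  if (!is.finite(cur$lp)) stop("initial point not evaluable for MALA")
  state <- list(theta = theta0, log_target = cur$lp,
                grad = cur$gradient, fim = cur$fim)
  logeps <- log(ctl$mala_step)
  nacc <- 0L
  for (i in seq_len(n_iter)) {
    out <- mala_step(state, tfun, exp(logeps))
    state <- out$state
    nacc <- nacc + as.integer(out$accepted)
    logeps <- min(30, max(-30, logeps +
      i^(-ctl$decay) * (as.numeric(out$accepted) - ctl$acc_target)))
    trace[i, ] <- state$theta
    lp_trace[i] <- state$log_target
  }
  list(trace = trace, log_posterior = lp_trace,
       acceptance_rate = nacc / n_iter, step_size = exp(logeps))
}

run_pt <- function(target, init, n_iter, ctl, d, trace, lp_trace) {
  L <- nrow(init)
  betas <- init_ladder(L, ctl$beta_max)
  chains <- vector("list", L)
  for (l in seq_len(L)) {
    llpr <- target$ll_lpr(init[l, ])
    if (!is.finite(llpr[2])) stop("initial point lies outside the prior box")
    chains[[l]] <- new_chain(init[l, ], llpr, betas[l], d, ctl)
  }
  log_spacing <- if (L > 1) log(diff(betas)) else numeric(0)
  ll_lpr <- target$ll_lpr
  n_swap_prop <- 0L; n_swap_acc <- 0L
  use_mala <- ctl$pt_inner == "mala"
  for (i in seq_len(n_iter)) {
    for (l in seq_along(chains)) {
      if (use_mala) pt_mala_substep(chains[[l]], target, ctl, d, i)
      else step_rw(chains[[l]], ll_lpr, ctl, d)
    }
    L <- length(chains)
    if (L >= 2) {
      # swap proposals (inlined for speed; pt_swap() is the reference
      # implementation of the same rule)
      step_i <- i^(-ctl$decay)
      if (ctl$swap_strategy == "aa") {
        for (l in seq_len(L - 1)) {
          el <- chains[[l]]; em <- chains[[l + 1]]
          a <- (1 / betas[l] - 1 / betas[l + 1]) * (em$ll - el$ll)
          acc <- log(stats::runif(1)) < a
          if (acc) {
            tmp <- list(el$theta, el$ll, el$lpr, el$gf)
            el$theta <- em$theta; el$ll <- em$ll; el$lpr <- em$lpr; el$gf <- em$gf
            em$theta <- tmp[[1]]; em$ll <- tmp[[2]]; em$lpr <- tmp[[3]]; em$gf <- tmp[[4]]
            n_swap_acc <- n_swap_acc + 1L
          }
          n_swap_prop <- n_swap_prop + 1L
          log_spacing[l] <- min(18.4, max(-18.4, log_spacing[l] +
            step_i * ((if (acc) 1 else 0) - ctl$swap_target)))
        }
      } else {
        ll_now <- vapply(chains, function(e) e$ll, 0)
        pr <- pt_propose_ee(ll_now)
        l <- pr[1]; mth <- pr[2]
        el <- chains[[l]]; em <- chains[[mth]]
        a <- (1 / betas[l] - 1 / betas[mth]) * (em$ll - el$ll)
        acc <- log(stats::runif(1)) < a
        if (acc) {
          tmp <- list(el$theta, el$ll, el$lpr, el$gf)
          el$theta <- em$theta; el$ll <- em$ll; el$lpr <- em$lpr; el$gf <- em$gf
          em$theta <- tmp[[1]]; em$ll <- tmp[[2]]; em$lpr <- tmp[[3]]; em$gf <- tmp[[4]]
          n_swap_acc <- n_swap_acc + 1L
        }
        n_swap_prop <- n_swap_prop + 1L
        if (mth == l + 1L)
          log_spacing[l] <- min(18.4, max(-18.4, log_spacing[l] +
            step_i * ((if (acc) 1 else 0) - ctl$swap_target)))
      }
      betas <- cumsum(c(1, exp(log_spacing)))
      for (l in seq_len(L)) {
        e <- chains[[l]]
        e$beta <- betas[l]
        e$lt <- e$ll / betas[l] + e$lpr
      }
      # adaptive chain count: drop the hottest chain when its log-beta
      # spacing collapses
      if (ctl$adaptive_temps && L > 2 &&
          (log(betas[L]) - log(betas[L - 1])) < ctl$spacing_threshold) {
        chains[[L]] <- NULL
        betas <- betas[-L]
        log_spacing <- log_spacing[-(L - 1)]
      }
    }
    trace[i, ] <- chains[[1]]$theta
    lp_trace[i] <- chains[[1]]$ll + chains[[1]]$lpr
  }
  list(trace = trace, log_posterior = lp_trace,
       acceptance_rate = chains[[1]]$nacc / n_iter,
       swap_rate = if (n_swap_prop > 0) n_swap_acc / n_swap_prop else NA_real_,
       ladder = betas)
}

# MALA substep on a tempered target (gradient and metric scaled by 1/beta).
pt_mala_substep <- function(e, target, ctl, d, i) {
  tfun <- function(th) {
    v <- target$ll_lpr(th)
    if (!is.finite(v[2])) return(list(lp = -Inf, gradient = NULL, fim = NULL))
    gf <- tryCatch(target$grad_fim(th), error = function(err) NULL)
    if (is.null(gf)) return(list(lp = -Inf, gradient = NULL, fim = NULL))
    list(lp = v[1] / e$beta + v[2], gradient = gf$gradient / e$beta,
         fim = gf$fim / e$beta + diag(1e-10, d))
  }
  if (is.null(e$gf)) {
    cur <- tfun(e$theta)
    e$gf <- list(grad = cur$gradient, fim = cur$fim)
    e$lt <- cur$lp
  }
  state <- list(theta = e$theta, log_target = e$lt,
                grad = e$gf$grad, fim = e$gf$fim)
  out <- mala_step(state, tfun, exp(e$logeps))
  if (out$accepted) {
    e$theta <- out$state$theta
    e$lt <- out$state$log_target
    e$gf <- list(grad = out$state$grad, fim = out$state$fim)
    v <- target$ll_lpr(e$theta)
    e$ll <- v[1]; e$lpr <- v[2]
    e$nacc <- e$nacc + 1L
  }
  e$iter <- e$iter + 1L
  e$logeps <- min(30, max(-30, e$logeps +
    i^(-ctl$decay) * (as.numeric(out$accepted) - 0.574)))
  invisible(e)
}

run_phs <- function(target, init, n_iter, ctl, d, trace, lp_trace) {
  K <- nrow(init) - 1L
  if (K < 1) stop("PHS requires at least one auxiliary chain")
  main <- local({
    llpr <- target$ll_lpr(init[1, ])
    if (!is.finite(llpr[2])) stop("initial point lies outside the prior box")
    list(theta = init[1, ], ll = llpr[1], lpr = llpr[2])
  })
  aux <- vector("list", K)
  for (k in seq_len(K)) {
    llpr <- target$ll_lpr(init[k + 1, ])
    if (!is.finite(llpr[2])) stop("initial point lies outside the prior box")
    aux[[k]] <- new_chain(init[k + 1, ], llpr, 1, d, ctl)
  }
  ll_lpr <- target$ll_lpr
  n_swaps <- 0L
  for (i in seq_len(n_iter)) {
    for (k in seq_len(K)) step_rw(aux[[k]], ll_lpr, ctl, d)
    j <- sample.int(K, 1)
    e <- aux[[j]]
    tmp <- list(theta = e$theta, ll = e$ll, lpr = e$lpr)
    e$theta <- main$theta; e$ll <- main$ll; e$lpr <- main$lpr
    e$lt <- e$ll + e$lpr
    main <- tmp
    n_swaps <- n_swaps + 1L
    trace[i, ] <- main$theta
    lp_trace[i] <- main$ll + main$lpr
  }
  list(trace = trace, log_posterior = lp_trace,
       acceptance_rate = mean(vapply(aux, function(e) e$nacc, 0)) / n_iter,
       swap_acceptance_count = n_swaps)
}

#' @export
print.sampler_run <- function(x, ...) {
  cat("<sampler_run> ", x$algorithm, " on ", x$problem,
      " (", x$n_iter, " iterations)\n", sep = "")
  cat("  acceptance rate: ", round(x$acceptance_rate, 3),
      ", cpu seconds: ", round(x$cpu_seconds, 2), "\n", sep = "")
  if (!is.null(x$ladder))
    cat("  final ladder: ", paste(signif(x$ladder, 3), collapse = ", "), "\n")
  invisible(x)
}
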