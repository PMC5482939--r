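# Chain initialization: prior sampling (RND) and multi-start local
# optimization (MS).

#' Draw starting points from the prior
#'
#' Independent uniform draws from the prior box, one row per point.
#'
#' @param problem a [benchmark_problem()] or [custom_target()].
#' @param n_points number of points (>= 1).
#' @param seed RNG seed; the caller's RNG state is untouched when given.
#' @return an `n_points x d` matrix.
#' @export
init_from_prior <- function(problem, n_points, seed = NULL) {
  stopifnot(n_points >= 1)
  if (inherits(problem, "benchmark_problem")) {
    lower <- problem$theta_min; upper <- problem$theta_max
  } else {
    lower <- problem$lower; upper <- problem$upper
  }
  d <- length(lower)
  pts <- with_seed(seed,
    matrix(stats::runif(n_points * d, rep(lower, each = n_points),
                        rep(upper, each = n_points)), nrow = n_points))
  colnames(pts) <- names(lower)
  pts
}

#' Multi-start local optimization of the log-posterior
#'
#' Each start draws a point from the prior and maximizes the log-posterior
#' with a bounded quasi-Newton method (`L-BFGS-B`), using analytic gradients
#' from [sensitivities()] where the model supports them. The result is a map
#' of the local optima of the posterior, sorted by final log-posterior
#' (best first).
#'
#' @param problem a [benchmark_problem()].
#' @param data dataset tibble.
#' @param n_starts number of starts.
#' @param seed RNG seed for the prior draws.
#' @param maxit optimizer iteration cap per start.
#' @param use_gradient use analytic gradients (`NULL` = auto: on when the
#'   model declares a closed-form solution or identity observation).
#' @return a tibble of class `multistart_result` with one row per start:
#'   `start` (list of initial theta), `theta` (list of optimized theta),
#'   `log_posterior`, `converged`, `iterations`; sorted by `log_posterior`
#'   descending. Attribute `cpu_seconds` holds the total optimization time.
#' @export
multistart_optimize <- function(problem, data, n_starts = 100, seed = NULL,
                                maxit = 1000, use_gradient = NULL) {
  stopifnot(n_starts >= 1)
  post <- make_posterior(problem, data)
  lower <- post$lower; upper <- post$upper
  d <- post$d
  if (is.null(use_gradient))
    use_gradient <- !is.null(problem$model$solution_sens)
  starts <- init_from_prior(problem, n_starts, seed)

  fn <- function(th) {
    v <- post$lp(th)
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- if (use_gradient) function(th) {
    g <- tryCatch(post$grad_fim(th)$gradient, error = function(e) NULL)
    if (is.null(g) || !all(is.finite(g))) numeric(d) else -g
  } else NULL

  t0 <- proc.time()
  rows <- lapply(seq_len(n_starts), function(s) {
    res <- tryCatch(
      stats::optim(starts[s, ], fn = fn, gr = gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res))
      return(tibble::tibble(start = list(starts[s, ]), theta = list(NULL),
                            log_posterior = -Inf, converged = FALSE,
                            iterations = NA_integer_))
    tibble::tibble(start = list(starts[s, ]), theta = list(res$par),
                   log_posterior = -res$value,
                   converged = res$convergence == 0,
                   iterations = res$counts[["function"]])
  })
  cpu <- sum((proc.time() - t0)[c("user.self", "sys.self")], na.rm = TRUE)
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$log_posterior))
  if (all(!is.finite(out$log_posterior))) stop("all optimization starts failed")
  attr(out, "cpu_seconds") <- cpu
  class(out) <- c("multistart_result", class(out))
  out
}

# Collapse near-duplicate optima (theta distance < tol, scaled by box width).
collapse_optima <- function(ms, lower, upper, tol = 1e-4) {
  ok <- which(is.finite(ms$log_posterior))
  keep <- integer(0)
  width <- upper - lower
  for (i in ok) {
    th <- ms$theta[[i]]
    dup <- FALSE
    for (j in keep) {
      if (max(abs((th - ms$theta[[j]]) / width)) < tol) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  ms[keep, , drop = FALSE]
}

#' Serialize multi-start results to JSON
#'
#' One record per start: initial point, optimized point, final
#' log-posterior, convergence flag and iteration count.
#'
#' @param ms a [multistart_optimize()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multistart <- function(ms, path) {
  recs <- lapply(seq_len(nrow(ms)), function(i)
    list(start = unname(ms$start[[i]]),
         theta = if (is.null(ms$theta[[i]])) NULL else unname(ms$theta[[i]]),
         log_posterior = ms$log_posterior[i],
         converged = ms$converged[i],
         iterations = ms$iterations[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Starting points from multi-start optimization results
#'
#' For a single chain, returns the optimum with the highest posterior
#' probability. For multi-chain configurations, near-duplicate optima are
#' collapsed, optima within `delta` log-posterior units of the best are
#' retained, and `n_chains` starting points are sampled uniformly from the
#' retained optima (with replacement when fewer optima than chains remain).
#'
#' @param ms a [multistart_optimize()] result.
#' @param n_chains number of starting points required.
#' @param delta log-posterior filter width (retain optima with
#'   `log_posterior >= best - delta`).
#' @param seed RNG seed for the uniform sampling.
#' @param dedup_tol scaled theta-distance below which two optima are
#'   considered the same before filtering.
#' @param lower,upper prior box bounds used for duplicate scaling; taken
#'   from the attribute-free thetas' range when omitted.
#' @return an `n_chains x d` matrix of starting points.
#' @export
init_from_multistart <- function(ms, n_chains, delta = 10, seed = NULL,
                                 dedup_tol = 1e-4, lower = NULL, upper = NULL) {
  stopifnot(nrow(ms) >= 1, n_chains >= 1)
  ok <- ms[is.finite(ms$log_posterior), , drop = FALSE]
  if (nrow(ok) == 0) stop("no finite optimization results")
  d <- length(ok$theta[[1]])
  if (is.null(lower)) {
    thmat <- do.call(rbind, ok$theta)
    lower <- apply(thmat, 2, min); upper <- apply(thmat, 2, max)
    upper <- pmax(upper, lower + 1)
  }
  if (n_chains == 1)
    return(matrix(ok$theta[[1]], nrow = 1,
                  dimnames = list(NULL, names(ok$theta[[1]]))))
  uniq <- collapse_optima(ok, lower, upper, dedup_tol)
  best <- max(uniq$log_posterior)
  retained <- uniq[uniq$log_posterior >= best - delta, , drop = FALSE]
  idx <- with_seed(seed,
    sample.int(nrow(retained), n_chains, replace = TRUE))
  out <- do.call(rbind, retained$theta[idx])
  out
}
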