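# Shared fixtures: toy targets, AR(1) series, synthetic runs.

# AR(1) series with unit innovation variance, stationary start.
ar1_series <- function(n, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(max(1 - rho^2, 1e-12))
  for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  x
}

# A benchmark problem whose observable is constant, for likelihood
# arithmetic with hand-computable values. theta = (a, sigma); `a` is inert.
const_problem <- function(value = 0) {
  m <- ode_model("const", n_x = 1, n_y = 1, n_eta = 1,
                 rhs = function(x, t, eta) 0,
                 initial_state = function(eta) value,
                 observation = function(x, t, eta) x,
                 parameter_names = c("a", "sigma"),
                 solution = function(times, eta) {
                   v <- matrix(value, length(times), 1)
                   list(x = v, y = v)
                 })
  benchmark_problem(m, theta_min = c(-1, 1e-3), theta_max = c(1, 10),
                    theta_true = c(0, 1), n_t = 2, t_interval = c(0, 1))
}

const_dataset <- function(values, times = seq_along(values)) {
  d <- tibble::tibble(time = times, y1 = values)
  class(d) <- c("bench_dataset", class(d))
  d
}

# Continuous embedding of a two-state target on [0, 1]: density 2/3 on
# [0, 0.5), 1/3 on [0.5, 1]. Occupation of the left cell is exactly 2/3.
two_state_target <- function() {
  custom_target(function(th) if (th[1] < 0.5) log(2) else 0,
                lower = 0, upper = 1, name = "two-state",
                gradient = function(th) 0,
                fim = function(th) matrix(1, 1, 1))
}

# Correlated 2-D Gaussian, unit variances, correlation rho, on a wide box.
gauss2d_target <- function(rho = 0.9) {
  prec <- solve(matrix(c(1, rho, rho, 1), 2))
  custom_target(function(th) -0.5 * drop(th %*% prec %*% th),
                lower = c(-10, -10), upper = c(10, 10), name = "gauss2d",
                gradient = function(th) -drop(prec %*% th),
                fim = function(th) prec)
}

# Fabricate a sampler_run for pipeline tests.
fake_run <- function(trace, scenario = "s", cpu_seconds = 1,
                     log_posterior = NULL) {
  trace <- as.matrix(trace)
  if (is.null(log_posterior)) log_posterior <- -rowSums(trace^2) / 2
  structure(list(trace = trace, log_posterior = log_posterior,
                 acceptance_rate = 0.3, cpu_seconds = cpu_seconds,
                 algorithm = "am", settings = list(), seed = 1,
                 problem = "synthetic", scenario = scenario,
                 n_iter = nrow(trace)),
            class = "sampler_run")
}

# Mode-visit indicator for the mRNA transfection problem: TRUE when the
# trace contains points on both sides of the beta = delta diagonal by a
# clear margin.
visits_both_modes <- function(trace, margin = 0.1) {
  s <- trace[, "log10_beta"] - trace[, "log10_delta"]
  any(s > margin) && any(s < -margin)
}
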