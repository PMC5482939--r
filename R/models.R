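#' @importFrom stats rnorm runif setNames
NULL

# Run code with a temporary RNG state when `seed` is given; the caller's
# RNG stream is untouched either way.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define an ODE model
#'
#' An `ode_model` bundles the vector field of a dynamical system together with
#' its initial-state map, observation map and parameter metadata. The full
#' parameter vector of an estimation problem is `theta = c(eta, sigma)`:
#' the `n_eta` dynamic parameters followed by one noise standard deviation
#' per observable. Parameters flagged `"log10"` in `scale` are stored and
#' sampled as log10 values and transformed back before the model functions
#' see them.
#'
#' Models may optionally declare a closed-form solution (`solution`) and its
#' observable sensitivities (`solution_sens`); when present these are used in
#' place of numerical integration, which is orders of magnitude faster and is
#' verified against the numerical route in the test suite.
#'
#' @param name short identifier.
#' @param n_x,n_y,n_eta state, observable and dynamic-parameter counts.
#' @param rhs `function(x, t, eta)` returning the length-`n_x` derivative.
#' @param initial_state `function(eta)` returning the length-`n_x` initial state.
#' @param observation `function(x, t, eta)` mapping an `n_t x n_x` state matrix
#'   to an `n_t x n_y` observable matrix.
#' @param parameter_names labels for all `n_eta + n_y` parameters.
#' @param scale per-parameter `"linear"` or `"log10"` flags.
#' @param solution optional `function(times, eta)` returning
#'   `list(x = <n_t x n_x>, y = <n_t x n_y>)` analytically.
#' @param solution_sens optional `function(times, eta)` returning an
#'   `n_t x n_y x n_eta` array of observable sensitivities d y / d eta.
#' @param numeric_sim optional override for the numerical integration route
#'   (same contract as `solution`, plus `rtol`/`atol` arguments); used by
#'   models whose dynamics are only piecewise smooth.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(name, n_x, n_y, n_eta, rhs, initial_state, observation,
                      parameter_names, scale = rep("linear", n_eta + n_y),
                      solution = NULL, solution_sens = NULL, numeric_sim = NULL) {
  stopifnot(length(parameter_names) == n_eta + n_y,
            length(scale) == n_eta + n_y,
            all(scale %in% c("linear", "log10")))
  structure(list(name = name, n_x = n_x, n_y = n_y, n_eta = n_eta,
                 rhs = rhs, initial_state = initial_state,
                 observation = observation,
                 parameter_names = parameter_names, scale = scale,
                 solution = solution, solution_sens = solution_sens,
                 numeric_sim = numeric_sim),
            class = "ode_model")
}

#' Define a benchmark estimation problem
#'
#' Couples an [ode_model()] with a uniform prior box, the generating
#' parameters and the measurement design (number of equidistant time points
#' and measurement window).
#'
#' @param model an [ode_model()].
#' @param theta_min,theta_max prior box bounds, length `n_eta + n_y`.
#' @param theta_true generating parameter vector (or `NULL` for problems with
#'   experimental data).
#' @param n_t number of measurement time points.
#' @param t_interval measurement window `c(t_start, t_max)`.
#' @return an object of class `benchmark_problem`.
#' @export
benchmark_problem <- function(model, theta_min, theta_max, theta_true,
                              n_t, t_interval) {
  n_theta <- model$n_eta + model$n_y
  stopifnot(length(theta_min) == n_theta, length(theta_max) == n_theta,
            all(theta_min < theta_max),
            is.null(theta_true) ||
              (length(theta_true) == n_theta &&
                 all(theta_true >= theta_min & theta_true <= theta_max)),
            n_t >= 2, length(t_interval) == 2, t_interval[1] < t_interval[2])
  structure(list(model = model,
                 theta_min = setNames(as.numeric(theta_min), model$parameter_names),
                 theta_max = setNames(as.numeric(theta_max), model$parameter_names),
                 theta_true = if (is.null(theta_true)) NULL else
                   setNames(as.numeric(theta_true), model$parameter_names),
                 n_t = as.integer(n_t), t_interval = as.numeric(t_interval)),
            class = "benchmark_problem")
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat("<benchmark_problem> ", x$model$name, "\n", sep = "")
  cat("  states: ", x$model$n_x, ", observables: ", x$model$n_y,
      ", parameters: ", n_par(x), "\n", sep = "")
  cat("  n_t = ", x$n_t, ", t in [", x$t_interval[1], ", ",
      x$t_interval[2], "]\n", sep = "")
  df <- data.frame(parameter = x$model$parameter_names,
                   min = x$theta_min, max = x$theta_max,
                   true = if (is.null(x$theta_true)) NA_real_ else x$theta_true,
                   scale = x$model$scale, row.names = NULL)
  print(df, ...)
  invisible(x)
}

n_par <- function(problem) problem$model$n_eta + problem$model$n_y

# Split theta into natural-scale dynamic parameters and noise sd's.
split_theta <- function(problem, theta) {
  m <- problem$model
  nat <- as.numeric(theta)
  lg <- m$scale == "log10"
  nat[lg] <- 10^nat[lg]
  list(eta = nat[seq_len(m$n_eta)], sigma = nat[m$n_eta + seq_len(m$n_y)])
}

#' Measurement time grid of a benchmark problem
#'
#' `n_t` equidistant points spanning the measurement window, endpoints
#' inclusive.
#' @param problem a [benchmark_problem()].
#' @return numeric vector of length `n_t`.
#' @export
measurement_times <- function(problem) {
  seq(problem$t_interval[1], problem$t_interval[2], length.out = problem$n_t)
}

# ---- built-in benchmark collection -----------------------------------------

# M1 mRNA transfection: dm/dt = -delta m, dG/dt = kTL m - beta G, m(t0) = m0.
# Only the product km0 = kTL * m0 is identifiable, so the scaled mRNA
# kTL * m is used as the first state. Protein G is observed. States are zero
# before the transfection time t0, and the degradation rates beta and delta
# are interchangeable in the output, which makes the posterior bimodal.
m1_solution <- function(times, eta) {
  t0 <- eta[1]; km0 <- eta[2]; beta <- eta[3]; delta <- eta[4]
  tp <- times - t0
  pre <- tp < 0
  tp[pre] <- 0
  m <- km0 * exp(-delta * tp)
  g <- if (abs(delta - beta) < 1e-12) km0 * tp * exp(-beta * tp)
       else km0 / (delta - beta) * (exp(-beta * tp) - exp(-delta * tp))
  if (any(pre)) { m[pre] <- 0; g[pre] <- 0 }
  list(x = cbind(m, g), y = matrix(g, ncol = 1))
}

m1_solution_sens <- function(times, eta) {
  t0 <- eta[1]; km0 <- eta[2]; beta <- eta[3]; delta <- eta[4]
  tp <- pmax(times - t0, 0)
  active <- times >= t0
  s <- array(0, dim = c(length(times), 1, 4))
  if (abs(delta - beta) < 1e-12) {
    eb <- exp(-beta * tp)
    y <- km0 * tp * eb
    s[, 1, 1] <- ifelse(active, km0 * eb * (beta * tp - 1), 0)
    s[, 1, 2] <- ifelse(active, tp * eb, 0)
    s[, 1, 3] <- ifelse(active, -km0 * tp^2 * eb / 2, 0)
    s[, 1, 4] <- s[, 1, 3]
  } else {
    eb <- exp(-beta * tp); ed <- exp(-delta * tp); dd <- delta - beta
    y <- km0 / dd * (eb - ed)
    s[, 1, 1] <- ifelse(active, km0 / dd * (beta * eb - delta * ed), 0)
    s[, 1, 2] <- ifelse(active, (eb - ed) / dd, 0)
    s[, 1, 3] <- ifelse(active, y / dd - km0 * tp * eb / dd, 0)
    s[, 1, 4] <- ifelse(active, -y / dd + km0 * tp * ed / dd, 0)
  }
  s
}

# Piecewise numerical route for M1 (states jump at the transfection time).
m1_numeric_sim <- function(times, eta, rtol, atol) {
  t0 <- eta[1]; km0 <- eta[2]; beta <- eta[3]; delta <- eta[4]
  x <- matrix(0, nrow = length(times), ncol = 2)
  after <- which(times >= t0)
  if (length(after)) {
    tt <- unique(c(t0, times[after]))
    sol <- deSolve::lsoda(y = c(km0, 0), times = tt,
                          func = function(t, x, p)
                            list(c(-delta * x[1], x[1] - beta * x[2])),
                          parms = NULL, rtol = rtol, atol = atol)
    x[after, ] <- sol[match(times[after], sol[, 1]), 2:3]
  }
  list(x = x, y = x[, 2, drop = FALSE])
}

make_m1_model <- function(name) {
  ode_model(
    name = name, n_x = 2, n_y = 1, n_eta = 4,
    rhs = function(x, t, eta) c(-eta[4] * x[1], x[1] - eta[3] * x[2]),
    initial_state = function(eta) c(eta[2], 0),
    observation = function(x, t, eta) x[, 2, drop = FALSE],
    parameter_names = c("log10_t0", "log10_km0", "log10_beta",
                        "log10_delta", "log10_sigma"),
    scale = rep("log10", 5),
    solution = m1_solution, solution_sens = m1_solution_sens,
    numeric_sim = m1_numeric_sim)
}

# M3 saturated growth: dx/dt = b1 - b2 x, x(0) = 0.
m3_solution <- function(times, eta) {
  b1 <- eta[1]; b2 <- eta[2]
  x <- if (abs(b2) < 1e-12) b1 * times else b1 / b2 * (1 - exp(-b2 * times))
  list(x = matrix(x, ncol = 1), y = matrix(x, ncol = 1))
}

m3_solution_sens <- function(times, eta) {
  b1 <- eta[1]; b2 <- eta[2]
  s <- array(0, dim = c(length(times), 1, 2))
  if (abs(b2) < 1e-12) {
    s[, 1, 1] <- times
    s[, 1, 2] <- -b1 * times^2 / 2
  } else {
    e <- exp(-b2 * times)
    s[, 1, 1] <- (1 - e) / b2
    s[, 1, 2] <- b1 * (times * e / b2 - (1 - e) / b2^2)
  }
  s
}

# M2 bistable switch default RHS: Wilhelm's minimal bistable mass-action
# system (S + Y -> 2X, 2X -> X + Y, X + Y -> Y + P, X -> P with S constant).
# The exact published variant is pluggable via `ode_model`.
m2_rhs <- function(x, t, eta) {
  k1 <- eta[1]; k2 <- eta[2]; k3 <- eta[3]; k4 <- eta[4]
  c(k1 * x[2] - k2 * x[1]^2 - k3 * x[1] * x[2] - k4 * x[1],
    k2 * x[1]^2 - k1 * x[2])
}

# M4 Hopf default RHS: three-species extended Brusselator-type mass-action
# network; the first two species form a Brusselator (supercritical Hopf in
# k4), the third is a linear reporter. Pluggable default.
m4_rhs <- function(x, t, eta) {
  kap <- eta[1]; k2 <- eta[2]; k3 <- eta[3]; k4 <- eta[4]; k5 <- eta[5]
  c(kap - (k2 + k4) * x[1] + k3 * x[1]^2 * x[2],
    k4 * x[1] - k3 * x[1]^2 * x[2],
    k2 * x[1] - k5 * x[3])
}

# M5 driven Van der Pol oscillator, autonomous embedding of the drive phase.
m5_rhs <- function(x, t, eta) {
  a <- eta[1]; d <- eta[2]; omega <- eta[3]
  c(x[2], a * (1 - x[1]^2) * x[2] - x[1] + d * cos(x[3]), omega)
}

# M6 Lorenz attractor.
m6_rhs <- function(x, t, eta) {
  alpha <- eta[1]; beta <- eta[2]; rho <- eta[3]
  c(alpha * (x[2] - x[1]), x[1] * (rho - x[3]) - x[2],
    x[1] * x[2] - beta * x[3])
}

identity_obs <- function(x, t, eta) x

#' Construct a built-in benchmark problem
#'
#' Returns one of the seven benchmark estimation problems (`M1a`, `M1b`,
#' `M2`, `M3`, `M4`, `M5`, `M6`) with its prior box, generating parameters,
#' and measurement design. `M1a` is the experimental-data variant of the
#' mRNA transfection model and carries no generating parameter vector; all
#' other problems are simulated-data benchmarks. M1 parameters are sampled
#' on the log10 scale; all other problems use linear scale.
#'
#' @param name one of `"M1a"`, `"M1b"`, `"M2"`, `"M3"`, `"M4"`, `"M5"`, `"M6"`.
#' @return a [benchmark_problem()].
#' @examples
#' make_benchmark("M3")
#' @export
make_benchmark <- function(name) {
  valid <- c("M1a", "M1b", "M2", "M3", "M4", "M5", "M6")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stop("unknown benchmark '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  switch(name,
    M1a = benchmark_problem(
      make_m1_model("M1a"),
      theta_min = c(-2, -5, -5, -5, -2),
      theta_max = c(1, 5, 5, 5, 2),
      theta_true = NULL, n_t = 150, t_interval = c(2, 27)),
    M1b = benchmark_problem(
      make_m1_model("M1b"),
      theta_min = c(-2, -5, -5, -5, -2),
      theta_max = c(1, 5, 5, 5, 2),
      theta_true = c(log10(2), log10(5), log10(0.8), log10(0.2), -1),
      n_t = 51, t_interval = c(0, 10)),
    M2 = benchmark_problem(
      ode_model("M2", n_x = 2, n_y = 2, n_eta = 6, rhs = m2_rhs,
                initial_state = function(eta) eta[5:6],
                observation = identity_obs,
                parameter_names = c("k1", "k2", "k3", "k4", "x0_1", "x0_2",
                                    "sigma1", "sigma2")),
      theta_min = c(2, 0, 0, 0, -3, -3, 1e-3, 1e-3),
      theta_max = c(20, 5, 5, 5, 3, 3, 1, 1),
      theta_true = c(8, 1, 1, 1, 2, 0.25, 0.3, 0.3),
      n_t = 101, t_interval = c(0, 200)),
    M3 = benchmark_problem(
      ode_model("M3", n_x = 1, n_y = 1, n_eta = 2,
                rhs = function(x, t, eta) eta[1] - eta[2] * x[1],
                initial_state = function(eta) 0,
                observation = identity_obs,
                parameter_names = c("b1", "b2", "sigma1"),
                solution = m3_solution, solution_sens = m3_solution_sens),
      theta_min = c(0, 0, 1e-3), theta_max = c(5, 5, 1e2),
      theta_true = c(1, 0.2, 0.03),
      n_t = 101, t_interval = c(0, 2.5)),
    M4 = benchmark_problem(
      ode_model("M4", n_x = 3, n_y = 3, n_eta = 8, rhs = m4_rhs,
                initial_state = function(eta) eta[6:8],
                observation = identity_obs,
                parameter_names = c("kappa", "k2", "k3", "k4", "k5",
                                    "x0_1", "x0_2", "x0_3",
                                    "sigma1", "sigma2", "sigma3")),
      theta_min = c(1, 0.8, 0.8, 0.8, 0.8, 0, 0, 0, 1e-2, 1e-2, 1e-2),
      theta_max = c(5, 1.2, 1.2, 1.2, 1.2, 2, 2, 2, 2, 2, 2),
      theta_true = c(3.8, 1, 1, 1, 1, 1, 1, 1, 0.75, 0.32, 0.46),
      n_t = 101, t_interval = c(0, 200)),
    M5 = benchmark_problem(
      ode_model("M5", n_x = 3, n_y = 3, n_eta = 6, rhs = m5_rhs,
                initial_state = function(eta) eta[4:6],
                observation = identity_obs,
                parameter_names = c("a", "d", "omega", "x0_1", "x0_2", "x0_3",
                                    "sigma1", "sigma2", "sigma3")),
      theta_min = c(2, 2, 2, -1, -1, -1, 1e-2, 1e-2, 1e-2),
      theta_max = c(8, 8, 8, 3, 3, 3, 2, 2, 2),
      theta_true = c(5, 5, 2.464, 0, 0, 1, 0.2, 0.8, 0.2),
      n_t = 101, t_interval = c(0, 200)),
    M6 = benchmark_problem(
      ode_model("M6", n_x = 3, n_y = 3, n_eta = 6, rhs = m6_rhs,
                initial_state = function(eta) eta[4:6],
                observation = identity_obs,
                parameter_names = c("alpha", "beta", "rho",
                                    "x0_1", "x0_2", "x0_3",
                                    "sigma1", "sigma2", "sigma3")),
      theta_min = c(0, 0, 10, 0, -10, -5, 1e-4, 1e-4, 1e-4),
      theta_max = c(20, 10, 30, 35, 10, 5, 1e2, 1e2, 1e2),
      theta_true = c(10, 8 / 3, 28, 26.61, -2.74, 0.95, 1, 1, 1),
      n_t = 101, t_interval = c(0, 200)))
}

# ---- simulation -------------------------------------------------------------

#' Simulate a benchmark problem
#'
#' Integrates the model at the given parameters and returns state and
#' observable trajectories at the requested times. Models that declare a
#' closed-form solution use it unless `method = "numeric"` forces the
#' integrator. Solver failures are returned as a flagged result, never as a
#' silently truncated trajectory.
#'
#' @param problem a [benchmark_problem()].
#' @param theta parameter vector on the sampling scale (defaults to
#'   `theta_true`).
#' @param times time grid (defaults to the problem's measurement grid).
#' @param method `"auto"` (closed form when available), `"closed"` or
#'   `"numeric"`.
#' @param rtol,atol integrator tolerances.
#' @return `list(times, x, y, failed)`; `x` is `n_t x n_x`, `y` is
#'   `n_t x n_y`. On failure `x` and `y` are `NULL` and `failed` is `TRUE`.
#' @export
simulate_problem <- function(problem, theta = problem$theta_true, times = NULL,
                             method = c("auto", "closed", "numeric"),
                             rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (is.null(theta)) stop("no theta given and problem has no theta_true")
  stopifnot(length(theta) == n_par(problem))
  if (is.null(times)) times <- measurement_times(problem)
  m <- problem$model
  eta <- split_theta(problem, theta)$eta

  use_closed <- (method == "closed") ||
    (method == "auto" && !is.null(m$solution))
  if (use_closed) {
    if (is.null(m$solution)) stop("model '", m$name, "' has no closed form")
    sol <- m$solution(times, eta)
    return(list(times = times, x = sol$x, y = sol$y, failed = FALSE))
  }

  if (!is.null(m$numeric_sim)) {
    out <- tryCatch(m$numeric_sim(times, eta, rtol, atol), error = function(e) NULL)
    if (is.null(out) || !all(is.finite(out$y)))
      return(list(times = times, x = NULL, y = NULL, failed = TRUE))
    return(list(times = times, x = out$x, y = out$y, failed = FALSE))
  }

  x0 <- m$initial_state(eta)
  t_start <- min(problem$t_interval[1], times[1])
  tt <- unique(c(t_start, times))
  sol <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = x0, times = tt,
                     func = function(t, x, p) list(m$rhs(x, t, eta)),
                     parms = NULL, rtol = rtol, atol = atol)),
    error = function(e) NULL)
  ok <- !is.null(sol) && nrow(sol) == length(tt) &&
    all(is.finite(sol[, -1, drop = FALSE])) &&
    attr(sol, "istate")[1] >= 0
  if (!ok) return(list(times = times, x = NULL, y = NULL, failed = TRUE))
  x <- sol[match(times, sol[, 1]), -1, drop = FALSE]
  dimnames(x) <- NULL
  y <- m$observation(x, times, eta)
  if (!all(is.finite(y)))
    return(list(times = times, x = NULL, y = NULL, failed = TRUE))
  list(times = times, x = x, y = y, failed = FALSE)
}

# ---- data generation and dataset I/O ----------------------------------------

#' Generate a noisy synthetic dataset
#'
#' Simulates the problem at `theta` on the problem's equidistant measurement
#' grid and adds independent Gaussian noise with the per-observable standard
#' deviations contained in `theta`.
#'
#' @param problem a [benchmark_problem()].
#' @param theta generating parameters on the sampling scale (defaults to
#'   `theta_true`).
#' @param seed RNG seed; the generated dataset is reproducible under a fixed
#'   seed and the caller's RNG state is left untouched when a seed is given.
#' @return a tibble of class `bench_dataset` with columns `time`,
#'   `y1`, ..., `yn_y`.
#' @export
generate_data <- function(problem, theta = problem$theta_true, seed = NULL) {
  if (is.null(theta)) stop("no theta given and problem has no theta_true")
  sim <- simulate_problem(problem, theta)
  if (sim$failed) stop("simulation failed at theta; cannot generate data")
  sigma <- split_theta(problem, theta)$sigma
  n_t <- problem$n_t; n_y <- problem$model$n_y
  noise <- with_seed(seed,
    matrix(rnorm(n_t * n_y), nrow = n_t) %*% diag(sigma, n_y))
  obs <- sim$y + noise
  colnames(obs) <- paste0("y", seq_len(n_y))
  out <- tibble::as_tibble(as.data.frame(obs))
  out <- tibble::add_column(out, time = sim$times, .before = 1)
  class(out) <- c("bench_dataset", class(out))
  out
}

# Extract the observation matrix (n_t x n_y) from a dataset.
dataset_matrix <- function(data) {
  as.matrix(data[, setdiff(names(data), "time"), drop = FALSE])
}

#' Read / write datasets as CSV
#'
#' The on-disk format is a plain CSV with header `time,y1,...,yn_y`; missing
#' observations are empty fields.
#'
#' @param data a dataset tibble as returned by [generate_data()].
#' @param path file path.
#' @return `read_dataset()` returns the dataset tibble; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a problem definition to JSON
#'
#' Writes the problem's parameter metadata (names, scales, prior box,
#' generating values) and measurement design to a JSON file; the model
#' functions themselves are code, not data, and are referenced by name.
#'
#' @param problem a [benchmark_problem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_problem <- function(problem, path) {
  m <- problem$model
  jsonlite::write_json(
    list(name = m$name, n_x = m$n_x, n_y = m$n_y, n_eta = m$n_eta,
         parameter_names = m$parameter_names, scale = m$scale,
         theta_min = unname(problem$theta_min),
         theta_max = unname(problem$theta_max),
         theta_true = if (is.null(problem$theta_true)) NULL else
           unname(problem$theta_true),
         n_t = problem$n_t, t_interval = problem$t_interval),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("dataset CSV must start with a 'time' column")
  out <- tibble::as_tibble(df)
  class(out) <- c("bench_dataset", class(out))
  out
}
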