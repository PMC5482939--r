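# Metropolis-Hastings kernel, adaptation, and the sampler variants.

test_that("mh_step accepts uphill moves and rejects zero-prior proposals", {
  tfun <- function(th) -0.5 * sum(th^2)
  state <- list(theta = 2, log_target = tfun(2))
  set.seed(1)
  for (k in 1:20) {
    out <- mh_step(state, tfun, function(th) 0) # propose the mode
    expect_true(out$accepted)
  }
  tbox <- function(th) if (abs(th) > 1) -Inf else 0
  state <- list(theta = 0, log_target = 0)
  for (k in 1:20) {
    out <- mh_step(state, tbox, function(th) 5) # outside the support
    expect_false(out$accepted)
    expect_equal(out$state$theta, 0)
  }
})

test_that("mh_step with a flip proposal reproduces the 2-state occupation", {
  tfun <- function(th) if (th < 0.5) log(2 / 3) else log(1 / 3)
  state <- list(theta = 0, log_target = tfun(0))
  set.seed(42)
  occ <- 0L
  n <- 1e5
  for (i in seq_len(n)) {
    state <- mh_step(state, tfun, function(th) 1 - th)$state
    if (state$theta < 0.5) occ <- occ + 1L
  }
  expect_lt(abs(occ / n - 2 / 3), 0.01)
})

test_that("NaN targets are rejected with a warning", {
  state <- list(theta = 0, log_target = 0)
  expect_warning(out <- mh_step(state, function(th) NaN, function(th) 1),
                 "NaN")
  expect_false(out$accepted)
})

test_that("adaptive proposal recursion equals the batch covariance", {
  set.seed(7)
  d <- 3
  ps <- proposal_state(d, eps = 1e-8, scheme = "dim", adapt_start = 10)
  xs <- matrix(rnorm(50 * d), ncol = d)
  for (i in 1:50) ps <- am_update(ps, xs[i, ])
  expect_lt(max(abs(proposal_empirical_cov(ps) - cov(xs))), 1e-10)
  # dim scaling: covariance = (2.38^2/d) Sigma + eps I
  d5 <- 5
  ps5 <- proposal_state(d5, eps = 1e-8, scheme = "dim", adapt_start = 10)
  xs5 <- matrix(rnorm(200 * d5), ncol = d5)
  for (i in 1:200) ps5 <- am_update(ps5, xs5[i, ])
  expect_equal(2.38^2 / 5, 1.13288, tolerance = 1e-4)
  expect_equal(ps5$covariance,
               (2.38^2 / 5) * proposal_empirical_cov(ps5) + diag(1e-8, d5),
               tolerance = 1e-12)
  # constant history falls back to eps I
  psc <- proposal_state(2, eps = 1e-8, scheme = "dim", adapt_start = 5)
  for (i in 1:40) psc <- am_update(psc, c(1, 2))
  expect_equal(psc$covariance, (2.38^2 / 2) * matrix(0, 2, 2) + diag(1e-8, 2))
})

test_that("acc scaling moves the scalar scale toward the target rate", {
  ps <- proposal_state(2, eps = 1e-8, scheme = "acc", adapt_start = 5)
  for (i in 1:50) ps <- am_update(ps, rnorm(2), accepted = TRUE)
  expect_gt(ps$logscale, 0) # all accepted: scale grows
  ps2 <- proposal_state(2, eps = 1e-8, scheme = "acc", adapt_start = 5)
  for (i in 1:50) ps2 <- am_update(ps2, rnorm(2), accepted = FALSE)
  expect_lt(ps2$logscale, 0)
})

test_that("delayed rejection acceptance matches a direct evaluation of the formula", {
  # replay dram_step's draws and recompute alpha2 by hand
  lt <- function(th) -0.5 * sum(th^2) # standard normal target
  R1 <- matrix(1, 1, 1) # unit-variance stage-1 proposal
  scale <- 5
  n_agree <- 0L
  for (s in 1:200) {
    set.seed(s)
    out <- dram_step(list(theta = 0, log_target = lt(0)), lt, R1,
                     n_tries = 2, scale = scale)
    set.seed(s)
    y1 <- 0 + rnorm(1)
    a1_x_y1 <- min(1, exp(lt(y1) - lt(0)))
    u1 <- runif(1)
    if (u1 < a1_x_y1) {
      expect_true(out$accepted)
      expect_equal(out$stages_used, 1L)
      expect_equal(out$state$theta, y1)
    } else {
      y2 <- 0 + rnorm(1) / scale
      a1_y2_y1 <- min(1, exp(lt(y1) - lt(y2)))
      q <- function(a, b) exp(-0.5 * (a - b)^2)
      alpha2 <- min(1, exp(lt(y2)) * q(y1, y2) * (1 - a1_y2_y1) /
                      (exp(lt(0)) * q(y1, 0) * (1 - a1_x_y1)))
      u2 <- runif(1)
      expect_equal(out$accepted, u2 < alpha2)
      expect_equal(out$stages_used, 2L)
      if (out$accepted) expect_equal(out$state$theta, y2, tolerance = 1e-12)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 200L)
})

test_that("first-stage acceptance short-circuits delayed rejection", {
  lt <- function(th) 0 # flat target: stage 1 always accepted
  set.seed(1)
  out <- dram_step(list(theta = 0, log_target = 0), lt, matrix(1, 1, 1))
  expect_true(out$accepted)
  expect_equal(out$stages_used, 1L)
})

test_that("MALA proposal and acceptance follow the Langevin rule", {
  # N(0,1) target: grad = -theta, G = 1; at theta = 1, eps = 1 the
  # proposal is N(0.5, 1)
  tfun <- function(th) list(lp = -0.5 * th^2, gradient = -th,
                            fim = matrix(1, 1, 1))
  for (s in 1:100) {
    set.seed(s)
    out <- mala_step(list(theta = 1, log_target = -0.5, grad = -1,
                          fim = matrix(1, 1, 1)), tfun, step_size = 1)
    set.seed(s)
    z <- rnorm(1)
    prop <- 0.5 + z
    u <- runif(1)
    mu_rev <- prop - prop / 2
    log_alpha <- (-0.5 * prop^2 - (-0.5)) +
      (-0.5 * (1 - mu_rev)^2) - (-0.5 * (prop - 0.5)^2)
    expect_equal(out$accepted, log(u) < log_alpha)
    expect_equal(out$state$theta, if (out$accepted) prop else 1,
                 tolerance = 1e-12)
  }
  # drift vanishes at the mode
  set.seed(2)
  out0 <- mala_step(list(theta = 0, log_target = 0, grad = 0,
                         fim = matrix(1, 1, 1)), tfun, step_size = 1e-8)
  expect_equal(out0$state$theta, 0, tolerance = 1e-6)
})

test_that("MALA samples a standard normal", {
  tgt <- custom_target(function(th) -0.5 * sum(th^2), lower = -10, upper = 10,
                       gradient = function(th) -th,
                       fim = function(th) matrix(1, 1, 1))
  r <- run_sampler(tgt, algorithm = "mala", n_iter = 1e5, seed = 1, init = 0.5)
  x <- r$trace[20001:1e5, 1]
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1), 0.03)
})

test_that("tempering swap mechanics follow the exchange rule", {
  expect_equal(pt_swap_probability(2, 2, -5, -50), 1) # equal temperatures
  expect_equal(pt_swap_probability(1, 2, -5, -10), exp(-2.5))
  expect_equal(round(pt_swap_probability(1, 2, -5, -10), 4), 0.0821)
  expect_equal(pt_propose_ee(c(-3.0, -7.1, -7.3)), c(2L, 3L))
  # fewer than 2 chains: no-op
  st <- list(list(theta = 1, ll = -1, lpr = 0))
  out <- pt_swap(st, 1)
  expect_identical(out$states, st)
  expect_length(out$accepted, 0)
  # swap exchanges full states
  set.seed(1)
  st2 <- list(list(theta = 1, ll = -1, lpr = 0),
              list(theta = 2, ll = -1, lpr = 0))
  out2 <- pt_swap(st2, c(1, 2)) # equal likelihood: probability 1
  expect_equal(out2$states[[1]]$theta, 2)
  expect_true(all(out2$accepted))
})

test_that("runs are reproducible and respect the prior box", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  r1 <- run_sampler(p, d, "am", n_iter = 500, seed = 9)
  r2 <- run_sampler(p, d, "am", n_iter = 500, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), 500)
  for (alg in c("am", "dram", "pt", "phs")) {
    ctl <- sampler_control(scheme = if (alg == "dram") "dim" else "acc",
                           n_temps = 3, n_aux = 2)
    r <- run_sampler(p, d, alg, n_iter = 400, seed = 3, control = ctl)
    expect_true(all(t(r$trace) >= p$theta_min & t(r$trace) <= p$theta_max),
                label = alg)
  }
})

test_that("PT with a single temperature degenerates exactly to AM(acc)", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  r_am <- run_sampler(p, d, "am", n_iter = 2000, seed = 5,
                      control = sampler_control(scheme = "acc"))
  r_pt <- run_sampler(p, d, "pt", n_iter = 2000, seed = 5,
                      control = sampler_control(n_temps = 1))
  expect_identical(r_am$trace, r_pt$trace)
})

test_that("the adapted temperature ladder stays sorted with beta_1 = 1", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  for (strat in c("aa", "ee")) {
    r <- run_sampler(p, d, "pt", n_iter = 3000, seed = 2,
                     control = sampler_control(n_temps = 5,
                                               swap_strategy = strat))
    expect_equal(r$ladder[1], 1)
    expect_true(all(diff(r$ladder) > 0))
  }
  # adaptive chain count never drops below 2 and keeps beta_1 = 1
  ra <- run_sampler(p, d, "pt", n_iter = 3000, seed = 2,
                    control = sampler_control(n_temps = 4,
                                              adaptive_temps = TRUE))
  expect_gte(length(ra$ladder), 2)
  expect_equal(ra$ladder[1], 1)
})

test_that("PHS always exchanges and needs at least one auxiliary", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  r <- run_sampler(p, d, "phs", n_iter = 300, seed = 4,
                   control = sampler_control(n_aux = 2))
  expect_equal(r$swap_acceptance_count, 300L) # never rejects
  expect_error(sampler_control(n_aux = 0))
})

test_that("invalid configurations are refused", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  expect_error(run_sampler(p, d, "dram", n_iter = 10, seed = 1,
                           control = sampler_control(scheme = "acc")),
               "dim")
})

test_that("acceptance-rate adaptation lands near its target", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  ms <- multistart_optimize(p, d, n_starts = 5, seed = 2)
  r <- run_sampler(p, d, "am", n_iter = 5e4, seed = 6,
                   init = init_from_multistart(ms, 1))
  expect_gt(r$acceptance_rate, 0.15)
  expect_lt(r$acceptance_rate, 0.35)
})
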