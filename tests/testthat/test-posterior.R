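# Prior, likelihood, posterior, tempering and sensitivities.

test_that("uniform box prior is 0 inside (boundary included) and -Inf outside", {
  m3 <- make_benchmark("M3")
  expect_equal(log_prior(m3, c(1, 0.2, 0.03)), 0)
  expect_equal(log_prior(m3, c(6, 0.2, 0.03)), -Inf)
  expect_equal(log_prior(m3, c(5, 5, 1e2)), 0) # closed box
  expect_equal(log_prior(m3, c(0, 0, 1e-3)), 0)
})

test_that("gaussian log-likelihood matches hand evaluation", {
  p <- const_problem(0)
  # one observation, zero residual, sigma = 1
  expect_equal(log_likelihood(p, const_dataset(0, times = 1), c(0, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(round(log_likelihood(p, const_dataset(0, times = 1), c(0, 1)), 4),
               -0.9189)
  # unit residual
  expect_equal(round(log_likelihood(p, const_dataset(1, times = 1), c(0, 1)), 4),
               -1.4189)
  # missing values are skipped
  d <- const_dataset(c(0, NA, 1))
  expect_equal(log_likelihood(p, d, c(0, 1)),
               2 * (-0.5 * log(2 * pi)) - 0.5)
})

test_that("log-likelihood is invariant under time-point permutation", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 2)
  perm <- sample(nrow(d))
  expect_equal(log_likelihood(p, d, p$theta_true),
               log_likelihood(p, d[perm, ], p$theta_true))
})

test_that("the transfection posterior is exactly symmetric in beta and delta", {
  p <- make_benchmark("M1b")
  d <- generate_data(p, seed = 4)
  th <- p$theta_true
  sw <- th; sw[c(3, 4)] <- th[c(4, 3)]
  expect_identical(log_likelihood(p, d, th), log_likelihood(p, d, sw))
  expect_identical(log_posterior(p, d, th)$log_posterior,
                   log_posterior(p, d, sw)$log_posterior)
})

test_that("points outside the box are rejected without touching the solver", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  post <- mcmcbench:::make_posterior(p, d)
  before <- post$n_eval
  expect_equal(post$lp(c(6, 0.2, 0.03)), -Inf)
  expect_equal(post$n_eval, before) # no likelihood evaluation
  ev <- log_posterior(p, d, c(6, 0.2, 0.03))
  expect_equal(ev$log_posterior, -Inf)
  expect_equal(ev$log_prior, -Inf)
  # inside the box the posterior equals the likelihood (flat prior)
  ev2 <- log_posterior(p, d, p$theta_true)
  expect_equal(ev2$log_posterior, ev2$log_likelihood + 0)
  expect_false(ev2$failed)
})

test_that("tempering scales the likelihood only", {
  p <- const_problem(0)
  d <- const_dataset(rep(0, 5))
  th <- c(0, 1)
  lp1 <- log_tempered_posterior(p, d, th, 1)
  expect_equal(lp1, log_posterior(p, d, th)$log_posterior)
  # ll = 5 * (-0.5 log 2pi); beta = 2 halves it
  expect_equal(log_tempered_posterior(p, d, th, 2),
               log_likelihood(p, d, th) / 2)
  expect_error(log_tempered_posterior(p, d, th, 0.5), "beta")
  # monotone non-decreasing in beta for a negative log-likelihood
  betas <- c(1, 2, 5, 20, 1e4)
  vals <- vapply(betas, function(b) log_tempered_posterior(p, d, th, b), 0)
  expect_true(all(diff(vals) >= 0))
  # large beta approaches the prior alone
  expect_equal(log_tempered_posterior(p, d, th, 1e12), 0, tolerance = 1e-6)
})

test_that("gradients match central finite differences", {
  fd_grad <- function(p, d, th, h = 1e-6) {
    vapply(seq_along(th), function(j) {
      tp <- th; tm <- th
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (log_likelihood(p, d, tp) - log_likelihood(p, d, tm)) / (2 * h)
    }, 0)
  }
  # closed-form sensitivity route (M3)
  p <- make_benchmark("M3"); d <- generate_data(p, seed = 1)
  g <- sensitivities(p, d, p$theta_true)$gradient
  expect_lt(max(abs(g - fd_grad(p, d, p$theta_true)) /
                  pmax(abs(g), 1)), 1e-4)
  # forward-sensitivity ODE route (M2, identity observation)
  p2 <- make_benchmark("M2"); d2 <- generate_data(p2, seed = 2)
  g2 <- sensitivities(p2, d2, p2$theta_true)$gradient
  expect_lt(max(abs(g2 - fd_grad(p2, d2, p2$theta_true, h = 1e-5)) /
                  pmax(abs(g2), 1)), 1e-3)
})

test_that("directional finite differences match the gradient at interior points", {
  p <- make_benchmark("M3"); d <- generate_data(p, seed = 6)
  set.seed(10)
  mid <- (p$theta_min + p$theta_max) / 2
  for (k in 1:10) {
    th <- p$theta_min + runif(3, 0.2, 0.8) * (p$theta_max - p$theta_min)
    g <- sensitivities(p, d, th)$gradient
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    h <- 1e-5
    fd <- (log_likelihood(p, d, th + h * v) -
             log_likelihood(p, d, th - h * v)) / (2 * h)
    expect_equal(sum(g * v), fd, tolerance = 1e-3)
  }
})

test_that("the Fisher information is symmetric and positive semidefinite", {
  p <- make_benchmark("M3"); d <- generate_data(p, seed = 1)
  set.seed(3)
  for (k in 1:5) {
    th <- p$theta_min + runif(3, 0.1, 0.9) * (p$theta_max - p$theta_min)
    fim <- sensitivities(p, d, th)$fim_raw
    expect_equal(fim, t(fim))
    expect_gt(min(eigen(fim, symmetric = TRUE)$values), -1e-8 * max(abs(fim)))
  }
})

test_that("transfection gradient mirrors under degradation-rate exchange", {
  p <- make_benchmark("M1b"); d <- generate_data(p, seed = 5)
  th <- p$theta_true
  th[1] <- 0.33 # keep t0 off the measurement grid (kink point)
  sw <- th; sw[c(3, 4)] <- th[c(4, 3)]
  g <- sensitivities(p, d, th)$gradient
  gs <- sensitivities(p, d, sw)$gradient
  expect_equal(unname(g[c(3, 4)]), unname(gs[c(4, 3)]), tolerance = 1e-10)
  expect_equal(unname(g[c(1, 2, 5)]), unname(gs[c(1, 2, 5)]), tolerance = 1e-10)
})

test_that("larger residuals never increase the likelihood at fixed sigma", {
  p <- const_problem(0)
  r <- seq(0, 3, by = 0.5)
  vals <- vapply(r, function(ri)
    log_likelihood(p, const_dataset(rep(ri, 4)), c(0, 1)), 0)
  expect_true(all(diff(vals) <= 0))
})
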