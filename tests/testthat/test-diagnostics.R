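# Spectral variance, Geweke, Gelman-Rubin-Brooks, burn-in, autocorrelation
# time and effective sample size.

test_that("spectral variance matches closed forms", {
  set.seed(1)
  n <- 1e5
  x <- rnorm(n)
  expect_lt(abs(spectral_variance(x) - 1 / n) / (1 / n), 0.2)
  y <- ar1_series(n, 0.9, seed = 2)
  # AR(1): S(0) = sigma2 (1+rho)/(1-rho) with stationary variance
  # sigma2/(1-rho^2); Var(mean) ~ 19 * var / n = 1/(1-rho)^2 / n
  target <- 1 / (1 - 0.9)^2 / n
  expect_lt(abs(spectral_variance(y) - target) / target, 0.25)
  # quadratic scaling
  expect_equal(spectral_variance(3 * x), 9 * spectral_variance(x),
               tolerance = 1e-10)
  # constant series flagged
  sv <- spectral_variance(rep(1, 100))
  expect_equal(as.numeric(sv), 0)
  expect_true(attr(sv, "constant"))
})

test_that("the Geweke test separates shifted means and is symmetric", {
  set.seed(3)
  g <- geweke_test(cbind(rnorm(2000), rnorm(2000, 10)),
                   chain_b = cbind(rnorm(2000), rnorm(2000)))
  expect_gt(g$p[1], 1e-4)
  expect_lt(g$p[2], 1e-10)
  # a chain equal to its own reversal: equal-half segments give z = 0
  x <- matrix(rnorm(1000), ncol = 1)
  xr <- x[nrow(x):1, , drop = FALSE]
  g2 <- geweke_test(rbind(x, xr), frac_a = 0.5, frac_b = 0.5)
  expect_equal(unname(g2$z), 0)
  # p monotone decreasing in |z|
  expect_true(all(order(abs(g$z)) == order(g$p, decreasing = TRUE)))
})

test_that("GRB distinguishes mixed from separated chains", {
  set.seed(4)
  a <- matrix(rnorm(2e4), ncol = 2)
  b <- matrix(rnorm(2e4), ncol = 2)
  same <- grb_diagnostic(list(a, b))
  expect_lt(same$mpsrf, 1.05)
  expect_true(all(same$psrf < 1.05))
  apart <- grb_diagnostic(list(a, b + 10))
  expect_gt(apart$mpsrf, 1.5)
  # identical copies: B = 0, psrf = sqrt((n-1)/n) <= 1
  n <- nrow(a)
  ident <- grb_diagnostic(list(a, a, a))
  expect_equal(unname(ident$psrf), rep(sqrt((n - 1) / n), 2),
               tolerance = 1e-10)
  expect_lte(max(ident$psrf), 1)
  # mpsrf never falls below its rotation-invariant floor
  expect_gte(same$mpsrf, (n - 1) / n)
  expect_error(grb_diagnostic(list(matrix(1, 50, 1), matrix(1, 50, 1))),
               "zero within-chain")
})

test_that("GRB is invariant under a common affine reparameterization", {
  set.seed(5)
  chains <- list(matrix(rnorm(6000), ncol = 3),
                 matrix(rnorm(6000, 0.05), ncol = 3))
  g1 <- grb_diagnostic(chains)
  A <- matrix(c(2, 0.5, 0, 0, 1, 0.3, 0, 0, 5), 3, 3)
  shift <- c(1, -2, 3)
  tchains <- lapply(chains, function(ch)
    sweep(ch %*% t(A), 2, shift, "+"))
  g2 <- grb_diagnostic(tchains)
  expect_equal(g1$mpsrf, g2$mpsrf, tolerance = 1e-8)
})

test_that("burn-in estimation finds changepoints and flags drift", {
  # stationary chains: the first candidate passes in most seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    bi <- estimate_burnin(matrix(rnorm(4000), ncol = 2))
    if (bi$n_bi == 0 && bi$converged) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # contaminated prefix: detection within one 5% grid step below the
  # changepoint (a window straddling the step can absorb it spectrally)
  set.seed(6)
  n <- 2000
  ch <- cbind(c(rnorm(0.2 * n, 10), rnorm(0.8 * n)), rnorm(n))
  bi <- estimate_burnin(ch)
  expect_gte(bi$n_bi, 0.15 * n)
  expect_true(bi$converged)
  # monotone in contamination length
  set.seed(7)
  noise <- matrix(rnorm(2 * n), ncol = 2)
  nbis <- vapply(c(0.1, 0.2, 0.4), function(f) {
    ch <- noise
    ch[seq_len(f * n), 1] <- ch[seq_len(f * n), 1] + 10
    estimate_burnin(ch)$n_bi
  }, 0)
  expect_true(all(diff(nbis) >= 0))
  # a pure trend never stabilizes
  set.seed(8)
  trend <- matrix(seq(0, 50, length.out = n) + rnorm(n, sd = 0.1), ncol = 1)
  bit <- estimate_burnin(trend)
  expect_false(bit$converged)
  expect_equal(bit$n_bi, n)
})

test_that("Sokal's estimator recovers AR(1) autocorrelation times", {
  n <- 1e5
  x <- ar1_series(n, 0, seed = 9)
  tau0 <- autocorr_time_sokal(x)
  expect_gte(tau0, 0.8)
  expect_lte(tau0, 1.3)
  y <- ar1_series(n, 0.9, seed = 10)
  tau9 <- autocorr_time_sokal(y)
  expect_lt(abs(tau9 - 19) / 19, 0.15)
  # thinning by the autocorrelation time removes the correlation
  thin <- y[seq(1, n, by = 19)]
  expect_lt(autocorr_time_sokal(thin), 2)
  expect_error(autocorr_time_sokal(rep(1, 200)), "constant")
})

test_that("ESS uses the maximum autocorrelation time across parameters", {
  n <- 1e4
  tr <- cbind(ar1_series(n, 0, seed = 11), ar1_series(n, 0.9, seed = 12))
  es <- effective_sample_size(tr)
  expect_equal(es$ess, n / max(es$tau))
  expect_lt(abs(es$ess - n / 19) / (n / 19), 0.35)
  expect_lte(es$ess, n)
  # i.i.d. trace: ESS near n
  es0 <- effective_sample_size(matrix(rnorm(2 * n), ncol = 2))
  expect_lt(abs(es0$ess - n) / n, 0.2)
  # permutation equivariance of the max rule
  es_perm <- effective_sample_size(tr[, 2:1])
  expect_equal(es$ess, es_perm$ess)
})

test_that("diagnose_run emits a flat report with ESS per second", {
  p <- make_benchmark("M3")
  d <- generate_data(p, seed = 1)
  ms <- multistart_optimize(p, d, n_starts = 5, seed = 2)
  r <- run_sampler(p, d, "am", n_iter = 4000, seed = 1,
                   init = init_from_multistart(ms, 1))
  rep <- diagnose_run(r)
  expect_named(rep, c("n_bi", "converged", "tau", "ess", "ess_per_second"))
  if (rep$converged) {
    expect_gt(rep$ess, 0)
    expect_equal(rep$ess_per_second, rep$ess / r$cpu_seconds)
  }
})
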