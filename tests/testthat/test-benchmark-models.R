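# Benchmark problem definitions, simulation and data generation.

test_that("built-in problems carry the published priors and true values", {
  m6 <- make_benchmark("M6")
  expect_equal(unname(m6$theta_true[["beta"]]), 8 / 3)

  m3 <- make_benchmark("M3")
  expect_equal(length(m3$theta_true), 3)
  expect_equal(unname(m3$theta_min), c(0, 0, 1e-3))
  expect_equal(unname(m3$theta_max), c(5, 5, 1e2))
  expect_equal(m3$n_t, 101L)
  expect_equal(m3$t_interval, c(0, 2.5))
  expect_equal(unname(m3$theta_true), c(1, 0.2, 0.03))

  m1b <- make_benchmark("M1b")
  expect_equal(unname(m1b$theta_true),
               c(log10(2), log10(5), log10(0.8), log10(0.2), -1))
  expect_equal(m1b$n_t, 51L)

  m1a <- make_benchmark("M1a")
  expect_null(m1a$theta_true)
  expect_equal(m1a$n_t, 150L)
  expect_equal(m1a$t_interval, c(2, 27))

  for (nm in c("M2", "M4", "M5")) {
    p <- make_benchmark(nm)
    expect_true(all(p$theta_min < p$theta_max))
    expect_true(all(p$theta_true >= p$theta_min & p$theta_true <= p$theta_max))
    expect_equal(length(p$theta_true), p$model$n_eta + p$model$n_y)
  }

  expect_error(make_benchmark("M9"), "valid names")
})

test_that("simulation honours initial conditions and closed forms", {
  m1b <- make_benchmark("M1b")
  # protein is zero at the transfection time t0 = 2
  s <- simulate_problem(m1b, times = 2)
  expect_equal(s$y[1, 1], 0)

  # closed-form oracle for the saturated-growth model
  m3 <- make_benchmark("M3")
  b1 <- 1; b2 <- 0.2
  s3 <- simulate_problem(m3, times = 2.5)
  expect_equal(s3$y[1, 1], b1 / b2 * (1 - exp(-b2 * 2.5)), tolerance = 1e-8)
  expect_equal(round(s3$y[1, 1], 4), 1.9673)
})

test_that("degradation-rate exchange leaves the transfection output invariant", {
  m1b <- make_benchmark("M1b")
  th <- m1b$theta_true
  th_swapped <- th
  th_swapped[c(3, 4)] <- th[c(4, 3)]
  times <- measurement_times(m1b)
  expect_identical(simulate_problem(m1b, th, times)$y,
                   simulate_problem(m1b, th_swapped, times)$y)
  # and for arbitrary draws
  set.seed(11)
  for (k in 1:10) {
    th <- init_from_prior(m1b, 1)[1, ]
    sw <- th; sw[c(3, 4)] <- th[c(4, 3)]
    expect_equal(simulate_problem(m1b, th, times)$y,
                 simulate_problem(m1b, sw, times)$y, tolerance = 1e-12)
  }
})

test_that("numerical integration agrees with the closed forms", {
  for (nm in c("M1b", "M3")) {
    p <- make_benchmark(nm)
    times <- measurement_times(p)
    yc <- simulate_problem(p, times = times, method = "closed")$y
    yn <- simulate_problem(p, times = times, method = "numeric")$y
    expect_lt(max(abs(yc - yn) / pmax(abs(yc), 1e-8)), 1e-6)
  }
})

test_that("all problems simulate at their true parameters, deterministically", {
  for (nm in c("M1b", "M2", "M3", "M4", "M5", "M6")) {
    p <- make_benchmark(nm)
    s1 <- simulate_problem(p)
    s2 <- simulate_problem(p)
    expect_false(s1$failed, label = nm)
    expect_equal(dim(s1$y), c(p$n_t, p$model$n_y))
    expect_identical(s1$y, s2$y) # bit-identical repeat
  }
})

test_that("solver failure is flagged, not silently truncated", {
  p <- make_benchmark("M6")
  # blow up the Lorenz system far outside its chaotic regime
  bad <- ode_model("diverge", n_x = 1, n_y = 1, n_eta = 1,
                   rhs = function(x, t, eta) eta[1] * x[1]^2,
                   initial_state = function(eta) 1,
                   observation = function(x, t, eta) x,
                   parameter_names = c("a", "sigma"))
  pb <- benchmark_problem(bad, c(0, 1e-3), c(1e3, 1), c(100, 0.1),
                          n_t = 11, t_interval = c(0, 10))
  capture.output(s <- simulate_problem(pb, c(100, 0.1)))
  expect_true(s$failed)
  expect_null(s$y)
})

test_that("generated datasets follow the measurement design", {
  m1b <- make_benchmark("M1b")
  d <- generate_data(m1b, seed = 1)
  expect_equal(nrow(d), 51)
  expect_equal(d$time, seq(0, 10, by = 0.2))

  # zero noise reproduces the trajectory exactly
  m3 <- make_benchmark("M3")
  th0 <- c(1, 0.2, 0)
  d0 <- generate_data(m3, theta = th0, seed = 5)
  expect_equal(d0$y1, simulate_problem(m3, th0)$y[, 1])

  # reproducibility and seed sensitivity
  expect_identical(generate_data(m3, seed = 7), generate_data(m3, seed = 7))
  expect_false(identical(generate_data(m3, seed = 7),
                         generate_data(m3, seed = 8)))
})

test_that("noise magnitude matches the generating standard deviation", {
  m3 <- make_benchmark("M3")
  y <- simulate_problem(m3)$y[, 1]
  set.seed(99)
  resid <- replicate(2000, generate_data(m3)$y1 - y)
  sds <- apply(resid, 1, sd)
  expect_lt(max(abs(sds - 0.03) / 0.03), 0.05)
})

test_that("datasets round-trip through CSV", {
  d <- generate_data(make_benchmark("M3"), seed = 3)
  d$y1[5] <- NA # missing values permitted
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})
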