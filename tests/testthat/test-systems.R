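test_that("logistic map iterates match hand arithmetic and stay in range", {
  expect_equal(iterate_logistic(0.1, 4, 2)$values, c(0.1, 0.36, 0.9216))
  # degenerate orbit through the maximum collapses to the fixed point 0
  expect_equal(iterate_logistic(0.5, 4, 3)$values, c(0.5, 1, 0, 0))
  orbit <- iterate_logistic(0.2, 4, 1000)$values
  expect_true(all(orbit >= 0 & orbit <= 1))
  expect_error(iterate_logistic(1.2, 4, 5), "x0")
  expect_error(iterate_logistic(0.3, Inf, 5), "mu")
})

test_that("Henon map iterates match hand arithmetic and flag escape", {
  expect_equal(iterate_henon(0, 0, 1.4, 0.3, n = 2)$values, c(0, 1, -0.4))
  x3 <- iterate_henon(0, 0, 1.4, 0.3, n = 3)$values[4]
  expect_equal(x3, 1 - 1.4 * 0.16 + 0.3)
  # long orbits from the attractor basin stay bounded
  expect_silent(long <- iterate_henon(0, 0, 1.4, 0.3, n = 5000))
  expect_lt(max(abs(long$values)), 2)
  expect_error(iterate_henon(5, 5, 1.4, 0.3, n = 10), "diverged at step")
})

test_that("flow integration matches an adaptive-step oracle", {
  spec <- system_spec("lorenz", n_transient = 0, n_samples = 101)
  mine <- integrate_flow(spec, state0 = c(x = 1, y = 1, z = 1))
  times <- seq(0, 1, by = 0.01)
  oracle <- deSolve::ode(c(x = 1, y = 1, z = 1), times,
                         multichaos:::lorenz_deriv, spec$params,
                         method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(mine$values - oracle[, "x"])), 1e-3)
})

test_that("Lorenz fixed point yields a constant series", {
  spec <- system_spec("lorenz", n_transient = 0, n_samples = 100)
  out <- integrate_flow(spec, state0 = c(x = 0, y = 0, z = 0))
  expect_true(all(out$values == 0))
})

test_that("RK4 step halving converges at fourth order on a short horizon", {
  run_to_1 <- function(dt) {
    n_to_1 <- round(1 / dt) + 1
    spec <- system_spec("lorenz", dt = dt, n_transient = 0,
                        n_samples = max(101, n_to_1))
    integrate_flow(spec, state0 = c(x = 1, y = 2, z = 3))$values[n_to_1]
  }
  ref <- run_to_1(0.0025)
  e1 <- abs(run_to_1(0.02) - ref)
  e2 <- abs(run_to_1(0.01) - ref)
  # halving dt should cut the error by roughly 2^4
  expect_gt(e1 / e2, 8)
})

test_that("Rossler default orbit stays bounded over 5000 kept samples", {
  out <- simulate_system("rossler")
  expect_lt(max(abs(out$values)), 100)
  expect_equal(length(out$values), 5000L)
})

test_that("noise injection is calibrated, seeded, and shape-preserving", {
  s <- simulate_system("logistic", n_samples = 5000, seed = 1)
  expect_identical(add_noise(s, 0)$values, s$values)
  n1 <- add_noise(s, 0.05, seed = 9)
  n2 <- add_noise(s, 0.05, seed = 9)
  expect_identical(n1$values, n2$values)
  added <- n1$values - s$values
  expect_lt(abs(sd(added) - 0.05) / 0.05, 0.05)
  expect_lt(abs(mean(added)), 3 * 0.05 / sqrt(5000))
  expect_equal(n1$dt, s$dt)
  expect_error(add_noise(s, -1), "sd")
})

test_that("map simulation is seed-reproducible and discards the transient", {
  a <- simulate_system("henon", n_samples = 300, seed = 42)
  b <- simulate_system("henon", n_samples = 300, seed = 42)
  expect_identical(a$values, b$values)
  c <- simulate_system("henon", n_samples = 300, seed = 43)
  expect_false(identical(a$values, c$values))
})
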