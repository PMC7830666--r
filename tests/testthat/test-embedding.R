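test_that("trajectory matrix obeys M = N - (m-1)J with delay-vector rows", {
  tr <- embed_series(1:10, m = 3, J = 2)
  expect_equal(dim(tr), c(6L, 3L))
  expect_equal(tr[1, ], c(1, 3, 5))
  # m = 1 reduces to the raw samples
  tr1 <- embed_series(1:10, m = 1, J = 1)
  expect_equal(as.numeric(tr1), 1:10)
  expect_error(embed_series(1:10, m = 4, J = 4), "N >= 13")
  # exhaustive small-N sweep
  for (N in 5:12) for (m in 1:4) for (J in 1:3) {
    if (N - (m - 1) * J < 1) next
    tr <- embed_series(seq_len(N), m = m, J = J)
    expect_equal(nrow(tr), N - (m - 1) * J)
    expect_equal(tr[nrow(tr), m], N)
  }
})

test_that("acf delay finds the quarter period of a sine and lag 1 of noise", {
  period <- 40
  s <- sin(2 * pi * (1:2000) / period)
  expect_equal(as.integer(estimate_delay_acf(s)), period / 4, tolerance = 0.11)
  set.seed(5)
  expect_equal(as.integer(estimate_delay_acf(rnorm(5000))), 1L)
  expect_error(estimate_delay_acf(rep(1, 100)), "constant")
})

test_that("MI delay matches a brute-force table-based oracle on a sine", {
  period <- 40
  x <- sin(2 * pi * (1:2000) / period)
  J <- estimate_delay_mi(x, lag_max = 30)
  mi_oracle <- vapply(1:30, function(j) bf_mi(x, j, 16L), numeric(1))
  expect_equal(attr(J, "mi"), mi_oracle, tolerance = 1e-10)
  # first minimum near the quarter period
  expect_lte(abs(as.integer(J) - period / 4), 4)
  set.seed(6)
  noise_J <- estimate_delay_mi(rnorm(3000), lag_max = 50)
  expect_lte(as.integer(noise_J), 5L)
  expect_lt(max(attr(noise_J, "mi")[-1]), 0.1)  # MI ~ 0 beyond lag 1
  expect_error(estimate_delay_mi(rep(2, 500)), "single bin")
})

test_that("correlation-integral delay agrees with MI on smooth signals", {
  period <- 48
  x <- sin(2 * pi * (1:2000) / period)
  J_ci <- estimate_delay_ci(x, lag_max = 30)
  J_mi <- estimate_delay_mi(x, lag_max = 30)
  expect_lte(abs(as.integer(J_ci) - as.integer(J_mi)), 2L)
  set.seed(7)
  expect_lte(as.integer(estimate_delay_ci(rnorm(2000), lag_max = 40)), 5L)
  # monotonically decaying dependence has no local minimum:
  # fallback plus warning
  set.seed(77)
  ar1 <- as.numeric(arima.sim(list(ar = 0.995), 600))
  expect_warning(estimate_delay_ci(ar1, lag_max = 8), "no local minimum")
})

test_that("delay estimators are invariant to affine rescaling", {
  s <- simulate_system("lorenz", n_samples = 2000, n_transient = 2000)
  x <- s$values
  y <- 100 * x - 7
  expect_equal(as.integer(estimate_delay_acf(x)),
               as.integer(estimate_delay_acf(y)))
  expect_equal(as.integer(estimate_delay_mi(x, lag_max = 60)),
               as.integer(estimate_delay_mi(y, lag_max = 60)))
  expect_equal(as.integer(estimate_delay_ci(x, lag_max = 60)),
               as.integer(estimate_delay_ci(y, lag_max = 60)))
})

test_that("Cao's method saturates on Lorenz and flags stochastic series", {
  s <- simulate_system("lorenz", n_samples = 5000)
  J <- suppressWarnings(estimate_delay_ci(s))
  cao <- estimate_dim_cao(s, J = J)
  expect_lte(cao$m, 5L)
  expect_gte(cao$m, 2L)
  # deterministic signal: E2 departs from 1 at low dimension
  expect_lt(min(cao$E2), 0.9)
  set.seed(8)
  # E1 of pure noise never saturates: warning expected, m_max returned
  noise <- suppressWarnings(estimate_dim_cao(rnorm(5000), J = 1, m_max = 8))
  expect_true(noise$flagged)
  expect_true(all(noise$E2 > 0.9 & noise$E2 < 1.1))
  expect_error(estimate_dim_cao(rnorm(300), J = 40, m_max = 10),
               "too short")
})

test_that("mean period recovers the period of a pure oscillation", {
  expect_equal(mean_period(sin(2 * pi * (1:4000) / 25)), 25, tolerance = 0.05)
})
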