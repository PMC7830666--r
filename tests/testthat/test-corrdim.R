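test_that("correlation sum matches brute-force pair counting exactly", {
  set.seed(31)
  traj <- matrix(rnorm(20 * 2), 20, 2)
  radii <- c(0.3, 0.8, 1.5, 3)
  cs <- correlation_sum(traj, radii, theiler = 1)
  for (i in seq_along(radii))
    expect_equal(cs$c_r[i], bf_corr_sum(traj, radii[i], 1))
})

test_that("correlation sum is monotone with saturated and empty extremes", {
  set.seed(32)
  traj <- matrix(runif(40 * 2), 40, 2)
  d <- dist(traj)
  radii <- sort(c(min(d) * 0.5, 0.2, 0.5, 1, max(d) * 1.01))
  cs <- correlation_sum(traj, radii, theiler = 0)
  expect_true(all(diff(cs$c_r) >= 0))
  expect_true(all(cs$c_r >= 0 & cs$c_r <= 1))
  expect_equal(cs$c_r[1], 0)                 # below minimum distance
  expect_equal(cs$c_r[length(radii)], 1)     # beyond the diameter
  expect_error(correlation_sum(traj, radii, theiler = 40), "pair")
  expect_error(correlation_sum(traj, c(2, 1), 0), "ascending")
})

test_that("D2 of i.i.d. uniform samples at m = 1 is about 1", {
  set.seed(33)
  d2 <- estimate_d2(runif(1500), embedding_params(1, 1), theiler = 1)
  expect_lt(abs(d2$d2 - 1), 0.15)
  expect_error(estimate_d2(rep(1, 600), embedding_params(1, 1)), "constant")
})

test_that("D2 of the Lorenz attractor falls in the known range", {
  # the true value is ~2.06; finite samples and the automatic scaling
  # window bias the Grassberger-Procaccia slope slightly low
  s <- simulate_system("lorenz", n_samples = 4000)
  d2 <- estimate_d2(s, embedding_params(3, 20))
  expect_gt(d2$d2, 1.6)
  expect_lt(d2$d2, 2.4)
})

test_that("added noise does not decrease estimated D2", {
  s <- simulate_system("henon", n_samples = 2000, seed = 34)
  clean <- estimate_d2(s, embedding_params(3, 1))$d2
  noisy <- estimate_d2(add_noise(s, 0.05, seed = 35),
                       embedding_params(3, 1))$d2
  expect_gte(noisy, clean - 0.05)
})
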