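test_that("p-norm distance matches direct arithmetic and rejects misuse", {
  expect_equal(pnorm_distance(c(3, 4), c(0, 0), 2), 5)
  expect_equal(pnorm_distance(c(3, 4), c(0, 0), 1), 7)
  expect_equal(pnorm_distance(c(3, 4), c(0, 0), 0.5), (sqrt(3) + 2)^2)
  expect_error(pnorm_distance(1:3, 1:2, 2), "dimension")
  expect_error(pnorm_distance(1, 2, 0), "positive")
})

test_that("p-norm distance is non-increasing in p on random vectors", {
  set.seed(11)
  ps <- c(0.25, 0.5, 1, 2, 4, 8)
  for (rep in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    d <- vapply(ps, function(p) pnorm_distance(u, v, p), numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("neighbor search equals the brute-force oracle for all p", {
  set.seed(12)
  traj <- matrix(rnorm(50 * 3), 50, 3)
  for (p in c(0.5, 1, 2, 5)) {
    got <- nearest_neighbors(traj, p = p, min_sep = 2)
    expect_equal(got$index, bf_nn(traj, p, 2))
  }
  # collinear toy, no exclusion
  toy <- matrix(c(0, 1, 3, 0, 0, 0), 3, 2)
  expect_equal(nearest_neighbors(toy, 2, 0)$index, c(2L, 1L, 2L))
  # exclusion window covering the whole matrix leaves no admissible pair
  expect_error(nearest_neighbors(traj, 2, min_sep = 50), "min_sep")
})

test_that("divergence curve equals the brute-force oracle stepwise", {
  set.seed(13)
  traj <- matrix(rnorm(10 * 2), 10, 2)
  attr(traj, "dt") <- 1
  for (p in c(0.5, 2)) {
    nb <- nearest_neighbors(traj, p, min_sep = 0)
    cv <- divergence_curve(traj, nb, p, k_max = 5, dt = 1)
    expect_equal(cv$y_p, bf_divergence(traj, nb$index, p, 5), tolerance = 1e-12)
  }
})

test_that("i = 0 of the divergence curve is the mean log initial separation", {
  set.seed(14)
  traj <- matrix(rnorm(30 * 2), 30, 2)
  nb <- nearest_neighbors(traj, 2, min_sep = 1)
  cv <- divergence_curve(traj, nb, 2, k_max = 3, dt = 0.5)
  expect_equal(cv$y_p[1], mean(log(nb$dist)) / 0.5)
})

test_that("duplicated rows are excluded from the average, not -Inf", {
  base <- matrix(c(0, 0, 1, 1, 2.5, 2.5, 4, 4), 4, 2, byrow = TRUE)
  traj <- rbind(base, base[1, ])          # exact duplicate of row 1
  nb <- nearest_neighbors(traj, 2, min_sep = 0)
  cv <- divergence_curve(traj, nb, 2, k_max = 2)
  expect_true(all(is.finite(cv$y_p[cv$n_valid > 0])))
  expect_lt(cv$n_valid[1], nrow(traj))    # zero-distance pairs dropped
})

test_that("GLLE fit recovers exact slopes and handles flat curves", {
  cv <- structure(data.frame(step = 0:30, time_s = 0:30,
                             y_p = 0.7 * (0:30) - 5,
                             n_valid = rep(10L, 31)),
                  p = 2, dt = 1, class = c("mc_divergence", "data.frame"))
  f <- fit_glle(cv, window = c(0, 30))
  expect_equal(f$glle, 0.7, tolerance = 1e-12)
  expect_equal(f$fit_r2, 1)
  flat <- cv; flat$y_p <- rep(2, 31)
  f0 <- fit_glle(flat, window = c(0, 30))
  expect_equal(f0$glle, 0)
  expect_error(fit_glle(cv, window = c(5, 3)), "i_lo < i_hi")
})

test_that("p = 2 pipeline is identical to a dedicated Euclidean oracle", {
  s <- simulate_system("henon", n_samples = 600, seed = 21)
  tr <- embed_series(s, m = 3, J = 1)
  nb <- nearest_neighbors(tr, 2, min_sep = 4)
  oracle <- bf_rosenstein_euclid(unclass(tr), min_sep = 4, k_max = 30)
  expect_equal(nb$index, as.integer(oracle$nn))
  cv <- divergence_curve(tr, nb, 2, k_max = 30)
  expect_equal(cv$y_p, oracle$y, tolerance = 1e-12)
})

test_that("logistic-map GLLE(2) recovers ln 2", {
  s <- simulate_system("logistic", seed = 3)
  sp <- glle_spectrum(s, embedding_params(2, 1), p_grid = c(2))
  expect_lt(abs(sp$glle - log(2)), 0.05)
})

test_that("spectrum width is max minus min, non-negative, zero iff flat", {
  s <- simulate_system("logistic", n_samples = 1000, seed = 4)
  sp <- glle_spectrum(s, embedding_params(2, 1), p_grid = c(0.5, 2, 6))
  expect_gte(spectrum_width(sp), 0)
  expect_equal(attr(sp, "width"), spectrum_width(sp))
  one <- glle_spectrum(s, embedding_params(2, 1), p_grid = 2)
  expect_equal(spectrum_width(one), 0)
  # synthetic two-entry spectrum
  fake <- sp[1:2, ]; fake$glle <- c(0.2, 0.5)
  class(fake) <- c("mc_spectrum", "data.frame")
  expect_equal(spectrum_width(fake), 0.3)
})

test_that("measurement quantization widens the spectrum via fractional orders", {
  # exact coordinate ties from a resolution floor are amplified by p < 1;
  # a clean double-precision orbit stays mono-chaotic
  s <- simulate_system("logistic", n_samples = 2000, seed = 9)
  q <- 1e-3
  sq <- mc_series(round(s$values / q) * q, dt = 1)
  w_clean <- attr(glle_spectrum(s, embedding_params(3, 1),
                                p_grid = c(0.1, 2)), "width")
  w_quant <- attr(glle_spectrum(sq, embedding_params(3, 1),
                                p_grid = c(0.1, 2)), "width")
  expect_lt(w_clean, 0.05)
  expect_gt(w_quant, 0.2)
})

test_that("unstable near-zero norm orders and bad grids are rejected", {
  s <- simulate_system("logistic", n_samples = 500, seed = 5)
  expect_error(glle_spectrum(s, embedding_params(2, 1), p_grid = c(0.01, 2)),
               "unstable")
  expect_error(glle_spectrum(s, embedding_params(2, 1), p_grid = c(2, 1)),
               "ascending")
  expect_error(glle_spectrum(s, embedding_params(2, 1), p_grid = numeric(0)),
               "empty")
})

test_that("neighbors must match the requested norm order", {
  s <- simulate_system("logistic", n_samples = 400, seed = 6)
  tr <- embed_series(s, m = 2, J = 1)
  nb <- nearest_neighbors(tr, 2, 2)
  expect_error(divergence_curve(tr, nb, 1, 10), "computed at p")
})
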