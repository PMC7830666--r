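# Brute-force oracles kept deliberately independent of the package's
# compiled kernels: plain-R double loops over the definitions.

bf_pdist <- function(u, v, p) sum(abs(u - v)^p)^(1 / p)

# O(M^2) nearest-neighbor search under a p-norm with temporal exclusion
bf_nn <- function(traj, p, min_sep) {
  M <- nrow(traj)
  idx <- integer(M)
  for (j in seq_len(M)) {
    best <- Inf; bestk <- NA_integer_
    for (k in seq_len(M)) {
      if (abs(k - j) <= min_sep) next
      d <- bf_pdist(traj[j, ], traj[k, ], p)
      if (d < best) { best <- d; bestk <- k }
    }
    idx[j] <- bestk
  }
  idx
}

# average log divergence of fixed neighbor pairs, definition-level
bf_divergence <- function(traj, nn, p, k_max, dt = 1) {
  M <- nrow(traj)
  vapply(0:k_max, function(i) {
    vals <- c()
    for (j in seq_len(M)) {
      jm <- nn[j]
      if (is.na(jm) || j + i > M || jm + i > M) next
      d <- bf_pdist(traj[j + i, ], traj[jm + i, ], p)
      if (d > 0) vals <- c(vals, log(d))
    }
    if (length(vals)) mean(vals) / dt else NA_real_
  }, numeric(1))
}

# dedicated Euclidean Rosenstein implementation (independent oracle for
# the p = 2 path): squared-distance search, stats::dist based
bf_rosenstein_euclid <- function(traj, min_sep, k_max, dt = 1) {
  M <- nrow(traj)
  dm <- as.matrix(dist(traj))
  dm[abs(row(dm) - col(dm)) <= min_sep] <- Inf
  nn <- apply(dm, 1L, which.min)
  y <- vapply(0:k_max, function(i) {
    ok <- seq_len(M - i)
    ok <- ok[nn[ok] + i <= M]
    d <- sqrt(rowSums((traj[ok + i, , drop = FALSE] -
                         traj[nn[ok] + i, , drop = FALSE])^2))
    d <- d[d > 0]
    if (length(d)) mean(log(d)) / dt else NA_real_
  }, numeric(1))
  list(nn = nn, y = y)
}

# histogram mutual information computed via base::table, not the package's
# tabulate() path
bf_mi <- function(x, J, n_bins) {
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  b <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  N <- length(x)
  tab <- table(b[1:(N - J)], b[(1 + J):N]) / (N - J)
  pi_ <- rowSums(tab); pj_ <- colSums(tab)
  s <- 0
  for (a in seq_along(pi_)) for (bb in seq_along(pj_)) {
    if (tab[a, bb] > 0) s <- s + tab[a, bb] * log(tab[a, bb] / (pi_[a] * pj_[bb]))
  }
  s
}

# pair-counting correlation sum, definition-level
bf_corr_sum <- function(traj, r, theiler) {
  M <- nrow(traj)
  hits <- 0L; total <- 0L
  for (j in seq_len(M - 1L)) for (k in (j + 1L):M) {
    if (k - j <= theiler) next
    total <- total + 1L
    if (sqrt(sum((traj[j, ] - traj[k, ])^2)) < r) hits <- hits + 1L
  }
  hits / total
}

# Feature simulator for stepwise-recovery checks.  The pathology scorer's
# +-100-scale coefficients on glle_4/glle_5 only make sense because those
# two features nearly cancel; simulate them as a shared base plus small
# independent parts so the linear predictor stays bounded.
sim_scorer_features <- function(n, seed) {
  set.seed(seed)
  f01 <- rnorm(n, 10, 0.8)
  f05 <- rnorm(n, 8, 0.2)
  f1 <- rnorm(n, 7, 0.15)
  base <- rnorm(n, 5, 0.1)
  f4 <- base + rnorm(n, 0, 0.01)
  f5 <- base + rnorm(n, 0, 0.01)
  f2 <- rnorm(n, 7, 0.5)
  f3 <- rnorm(n, 6, 0.5)
  fv <- data.frame(glle_0.1 = f01, glle_0.5 = f05, glle_1 = f1,
                   glle_2 = f2, glle_3 = f3, glle_4 = f4, glle_5 = f5,
                   check.names = FALSE)
  sc <- model1_scorer()
  eta <- sc$intercept + as.matrix(fv[names(sc$coefficients)]) %*%
    sc$coefficients
  eta <- eta - mean(eta)                 # centre so both classes occur
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  list(features = fv, labels = y)
}
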