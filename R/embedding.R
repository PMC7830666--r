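#' Delay-coordinate embedding parameters
#'
#' @param m embedding dimension (integer `>= 1`).
#' @param J time delay in samples (integer `>= 1`).
#'
#' @return An `embedding_params` list.
#' @examples
#' embedding_params(3, 2)
#' @export
embedding_params <- function(m, J) {
  m <- as.integer(m); J <- as.integer(J)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1", call. = FALSE)
  if (is.na(J) || J < 1L) stop("'J' must be an integer >= 1", call. = FALSE)
  structure(list(m = m, J = J), class = "embedding_params")
}

#' Build the delay-embedded trajectory matrix
#'
#' Reconstructs phase-space states from a scalar series: row `i` is the
#' delay vector \eqn{(x_i, x_{i+J}, \ldots, x_{i+(m-1)J})}, giving an
#' \eqn{M \times m} matrix with \eqn{M = N - (m-1) J} rows.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param params an [embedding_params], or `NULL` to pass `m` and `J`
#'   directly.
#' @param m,J embedding dimension and delay, used when `params` is `NULL`.
#'
#' @return A numeric matrix of class `mc_traj` with attributes `m`, `J`,
#'   `dt`.
#' @examples
#' tr <- embed_series(1:10, m = 3, J = 2)
#' dim(tr)      # 6 x 3
#' tr[1, ]      # 1 3 5
#' @export
embed_series <- function(ts, params = NULL, m = NULL, J = NULL) {
  ts <- as_mc_series(ts)
  if (is.null(params)) params <- embedding_params(m, J)
  x <- ts$values
  N <- length(x)
  m <- params$m; J <- params$J
  M <- N - (m - 1L) * J
  if (M < 1L)
    stop(sprintf(
      "series too short to embed: need N >= %d for m = %d, J = %d (have %d)",
      (m - 1L) * J + 1L, m, J, N), call. = FALSE)
  traj <- vapply(seq_len(m) - 1L,
                 function(k) x[(1L + k * J):(M + k * J)],
                 numeric(M))
  traj <- matrix(traj, nrow = M, ncol = m)
  structure(traj, m = m, J = J, dt = ts$dt, class = c("mc_traj", "matrix"))
}

scan_lag_max <- function(N, lag_max = NULL) {
  up <- max(2L, as.integer(floor(N / 4)))
  if (is.null(lag_max)) up else min(as.integer(lag_max), up)
}

#' Delay estimation from the autocorrelation function
#'
#' Returns the smallest lag at which the absolute autocorrelation first
#' drops to (nearly) zero.  If no lag below `N/4` qualifies, the lag of
#' minimum `|acf|` is returned with a warning.
#'
#' @param ts an [mc_series] or numeric vector (`N >= 50`, non-constant).
#' @param zero_tol tolerance below which `|acf|` counts as zero
#'   (default 0.05).
#' @param lag_max largest lag scanned (default `N/4`).
#'
#' @return Integer delay `J`; attribute `flagged` is `TRUE` when no
#'   near-zero crossing was found.
#' @examples
#' estimate_delay_acf(sin(2 * pi * (1:1000) / 40))  # about 10
#' @export
estimate_delay_acf <- function(ts, zero_tol = 0.05, lag_max = NULL) {
  ts <- as_mc_series(ts)
  x <- ts$values
  if (length(x) < 50L) stop("need at least 50 samples", call. = FALSE)
  if (sd(x) == 0) stop("autocorrelation undefined for a constant series",
                       call. = FALSE)
  lag_max <- scan_lag_max(length(x), lag_max)
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  hit <- which(abs(rho) <= zero_tol)
  if (length(hit)) {
    J <- hit[1L]
    flagged <- FALSE
  } else {
    J <- which.min(abs(rho))
    flagged <- TRUE
    warning(sprintf(
      "|acf| never fell below %g up to lag %d; returning lag of minimum |acf|",
      zero_tol, lag_max), call. = FALSE)
  }
  structure(as.integer(J), flagged = flagged)
}

# Histogram mutual information (nats) between x[t] and x[t + J] with
# equal-width bins over the sample range.
lagged_mi <- function(x, J, n_bins) {
  N <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("mutual information undefined: series occupies ",
                             "a single bin", call. = FALSE)
  b <- pmin(pmax(findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                              rightmost.closed = TRUE), 1L), n_bins)
  bi <- b[1:(N - J)]
  bj <- b[(1 + J):N]
  joint <- tabulate(bi + n_bins * (bj - 1L), nbins = n_bins * n_bins)
  joint <- joint / sum(joint)
  pi_ <- rowSums(matrix(joint, n_bins, n_bins))
  pj_ <- colSums(matrix(joint, n_bins, n_bins))
  pp <- outer(pi_, pj_)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

first_local_min <- function(v) {
  # smallest index that is a strict local minimum; index 1 qualifies when
  # v[1] < v[2] (the left neighbour, lag 0, is self-dependence and always
  # larger for these measures)
  n <- length(v)
  for (j in seq_len(n - 1L)) {
    left_ok <- if (j == 1L) TRUE else v[j] < v[j - 1L]
    if (left_ok && v[j] < v[j + 1L]) return(j)
  }
  NA_integer_
}

#' Delay estimation from the first minimum of mutual information
#'
#' Scans lags `1..N/4` and returns the smallest lag at a strict local
#' minimum of the histogram-based mutual information between `x[t]` and
#' `x[t+J]` (Fraser-Swinney criterion); falls back to the global minimum of
#' the scanned range, with a warning, if no local minimum exists.
#'
#' @param ts an [mc_series] or numeric vector (`N >= 200`).
#' @param n_bins number of equal-width histogram bins (default 16).
#' @param lag_max largest lag scanned (default `N/4`).
#'
#' @return Integer delay `J` with attribute `mi` holding the scanned curve.
#' @examples
#' estimate_delay_mi(sin(2 * pi * (1:1000) / 40))
#' @export
estimate_delay_mi <- function(ts, n_bins = 16L, lag_max = NULL) {
  ts <- as_mc_series(ts)
  x <- ts$values
  if (length(x) < 200L) stop("need at least 200 samples", call. = FALSE)
  lag_max <- scan_lag_max(length(x), lag_max)
  mi <- vapply(seq_len(lag_max), function(J) lagged_mi(x, J, n_bins),
               numeric(1))
  J <- first_local_min(mi)
  flagged <- FALSE
  if (is.na(J)) {
    J <- which.min(mi)
    flagged <- TRUE
    warning("no local minimum of mutual information below lag ", lag_max,
            "; returning the global minimum", call. = FALSE)
  }
  structure(as.integer(J), mi = mi, flagged = flagged)
}

#' Delay estimation from minima of the correlation integral
#'
#' Computes the correlation integral \eqn{C_m(J)} of the `m_probe`-dimensional
#' delay embedding at a fixed radius (the 10th percentile of pairwise
#' distances of the lag-1 embedding) and returns the smallest lag at a
#' strict local minimum, following the Liebert-Schuster observation that
#' these minima coincide with mutual-information minima at a fraction of
#' the cost.
#'
#' @param ts an [mc_series] or numeric vector (`N >= 200`).
#' @param m_probe probe embedding dimension (default 2).
#' @param lag_max largest lag scanned (default `N/4`).
#' @param n_ref at most this many reference points are used for the pairwise
#'   statistics (evenly strided subsample; default 1000).
#'
#' @return Integer delay `J` with attribute `ci` holding the scanned curve.
#' @examples
#' estimate_delay_ci(sin(2 * pi * (1:1000) / 40))
#' @export
estimate_delay_ci <- function(ts, m_probe = 2L, lag_max = NULL,
                              n_ref = 1000L) {
  ts <- as_mc_series(ts)
  x <- ts$values
  N <- length(x)
  if (N < 200L) stop("need at least 200 samples", call. = FALSE)
  if (sd(x) == 0) stop("correlation integral undefined for a constant series",
                       call. = FALSE)
  lag_max <- scan_lag_max(N, lag_max)
  m_probe <- as.integer(m_probe)

  stride_rows <- function(traj) {
    M <- nrow(traj)
    if (M <= n_ref) return(traj)
    traj[round(seq(1L, M, length.out = n_ref)), , drop = FALSE]
  }
  # fixed radius from the lag-1 probe embedding
  base <- stride_rows(embed_series(ts, m = m_probe, J = 1L))
  d0 <- dist(base)
  r0 <- as.numeric(quantile(d0, 0.10, names = FALSE))
  if (r0 <= 0) r0 <- min(d0[d0 > 0], na.rm = TRUE)

  ci_at <- function(J) {
    tr <- stride_rows(embed_series(ts, m = m_probe, J = J))
    mean(dist(tr) < r0)
  }

  # scan lazily: stop at the first confirmed strict local minimum
  vals <- numeric(0)
  J_hat <- NA_integer_
  for (J in seq_len(lag_max)) {
    vals[J] <- ci_at(J)
    if (J >= 2L) {
      jm <- J - 1L
      left_ok <- if (jm == 1L) TRUE else vals[jm] < vals[jm - 1L]
      if (left_ok && vals[jm] < vals[J]) { J_hat <- jm; break }
    }
    if ((m_probe - 1L) * (J + 1L) >= N) break
  }
  flagged <- FALSE
  if (is.na(J_hat)) {
    J_hat <- which.min(vals)
    flagged <- TRUE
    warning("no local minimum of the correlation integral below lag ",
            length(vals), "; returning the global minimum", call. = FALSE)
  }
  structure(as.integer(J_hat), ci = vals, flagged = flagged)
}

#' Minimum embedding dimension by Cao's method
#'
#' Computes Cao's E1 and E2 curves from ratios of mean nearest-neighbor
#' distances (maximum norm) between consecutive embedding dimensions.  The
#' embedding dimension is the point where E1 stops changing: the smallest
#' `d` at which the step to `E1(d+1)` falls below `sat_tol` while `E1(d)`
#' has already risen past `e1_floor`.  If no such point exists, the
#' smallest `d` with E1 at or above 0.95 for two consecutive dimensions is
#' used; failing that, `m_max` is returned with a warning.  The result is
#' never below 2 (a scalar embedding cannot separate norm orders).  E2
#' distinguishes deterministic signals from stochastic ones: for i.i.d.
#' noise E2 stays close to 1 at every dimension.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param J time delay in samples.
#' @param m_max largest dimension probed (`>= 3`; E1/E2 are defined up to
#'   `m_max - 1`).
#' @param sat_tol largest successive E1 change still counting as
#'   "stopped changing" (default 0.05).
#' @param e1_floor E1 level that must be reached before saturation is
#'   accepted (default 0.8, guarding against premature flat stretches).
#'
#' @return A list with elements `m` (selected dimension), `E1`, `E2`
#'   (curves over `d = 1..m_max-1`) and `flagged` (`TRUE` when E1 never
#'   saturated and `m_max` was returned).
#' @examples
#' s <- simulate_system("lorenz", n_samples = 1000, n_transient = 2000)
#' estimate_dim_cao(s, J = 10, m_max = 6)$m
#' @export
estimate_dim_cao <- function(ts, J, m_max = 10L, sat_tol = 0.05,
                             e1_floor = 0.8) {
  ts <- as_mc_series(ts)
  x <- ts$values
  J <- as.integer(J); m_max <- as.integer(m_max)
  if (m_max < 3L) stop("'m_max' must be at least 3", call. = FALSE)
  if (length(x) <= m_max * J + 1L)
    stop(sprintf("series too short for m_max = %d at J = %d: need N > %d",
                 m_max, J, m_max * J + 1L), call. = FALSE)
  e <- cao_e_cpp(x, J, m_max)
  E <- e[, 1L]; Estar <- e[, 2L]
  d_idx <- seq_len(m_max - 1L)
  E1 <- E[d_idx + 1L] / E[d_idx]
  E2 <- Estar[d_idx + 1L] / Estar[d_idx]
  flagged <- FALSE
  settled <- which(abs(diff(E1)) <= sat_tol & head(E1, -1L) >= e1_floor)
  if (length(settled)) {
    m_hat <- settled[1L]
  } else {
    sat <- E1 >= 0.95
    ok <- which(sat & c(sat[-1L], FALSE))
    if (length(ok)) {
      m_hat <- ok[1L]
    } else {
      m_hat <- m_max
      flagged <- TRUE
      warning("E1 did not saturate below m_max = ", m_max, call. = FALSE)
    }
  }
  list(m = max(2L, as.integer(m_hat)), E1 = E1, E2 = E2, flagged = flagged)
}

#' Mean period of a series from its power spectrum
#'
#' Reciprocal of the mean frequency of the raw periodogram, in samples.
#' Used as the default temporal exclusion window (Theiler window) for
#' nearest-neighbor searches, following the original Rosenstein
#' prescription.
#'
#' @param ts an [mc_series] or numeric vector.
#'
#' @return Mean period in samples (numeric scalar `>= 1`).
#' @examples
#' mean_period(sin(2 * pi * (1:1000) / 25))  # about 25
#' @export
mean_period <- function(ts) {
  ts <- as_mc_series(ts)
  x <- ts$values
  if (sd(x) == 0) return(1)
  sp <- spec.pgram(stats::ts(x), taper = 0, detrend = TRUE, plot = FALSE)
  mean_freq <- sum(sp$freq * sp$spec) / sum(sp$spec)  # cycles per sample
  max(1, 1 / mean_freq)
}

#' Estimate delay and embedding dimension for a series
#'
#' Convenience wrapper chaining one of the three delay estimators with
#' Cao's dimension estimate.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param delay_method `"acf"`, `"mi"` or `"ci"`.
#' @param m_max largest dimension probed by Cao's method.
#' @param ... forwarded to the chosen delay estimator.
#'
#' @return An [embedding_params] with attributes `cao` (full Cao output)
#'   and `delay_method`.
#' @examples
#' s <- simulate_system("henon", n_samples = 1000, seed = 4)
#' estimate_embedding(s, delay_method = "acf")
#' @export
estimate_embedding <- function(ts, delay_method = c("acf", "mi", "ci"),
                               m_max = 10L, ...) {
  ts <- as_mc_series(ts)
  delay_method <- match.arg(delay_method)
  J <- switch(delay_method,
              acf = estimate_delay_acf(ts, ...),
              mi  = estimate_delay_mi(ts, ...),
              ci  = estimate_delay_ci(ts, ...))
  # keep Cao feasible for the available length
  m_max_eff <- min(m_max, max(3L, (length(ts$values) - 2L) %/% as.integer(J)))
  cao <- estimate_dim_cao(ts, J = J, m_max = m_max_eff)
  out <- embedding_params(m = cao$m, J = as.integer(J))
  attr(out, "cao") <- cao
  attr(out, "delay_method") <- delay_method
  out
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(sprintf("<embedding_params> m = %d, J = %d\n", x$m, x$J))
  invisible(x)
}
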