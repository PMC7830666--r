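#' Minkowski p-norm distance between two state vectors
#'
#' \eqn{\|u - v\|_p = (\sum_k |u_k - v_k|^p)^{1/p}} for any real
#' \eqn{p > 0}.  For \eqn{p \ge 1} this is a true norm; for
#' \eqn{0 < p < 1} the triangle inequality fails and the quantity is a
#' "fractional norm", which emphasises small coordinate fluctuations.
#'
#' @param u,v numeric vectors of equal length.
#' @param p positive order.
#'
#' @return Non-negative scalar distance.
#' @examples
#' pnorm_distance(c(3, 4), c(0, 0), 2)    # 5
#' pnorm_distance(c(3, 4), c(0, 0), 1)    # 7
#' pnorm_distance(c(3, 4), c(0, 0), 0.5)  # (sqrt(3) + 2)^2
#' @export
pnorm_distance <- function(u, v, p) {
  if (length(u) != length(v))
    stop("'u' and 'v' must have the same dimension", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' must be a single positive number", call. = FALSE)
  sum(abs(u - v)^p)^(1 / p)
}

check_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0))
    stop("p-norm orders must be positive and finite", call. = FALSE)
  if (any(p <= 0.05))
    stop("p-norm orders at or below 0.05 are rejected: divergence ",
         "estimates become numerically unstable near p = 0", call. = FALSE)
  p
}

#' Nearest neighbor of every trajectory point under a p-norm
#'
#' For each row `j` of the trajectory matrix, finds the row `j'` minimising
#' the p-norm distance subject to the temporal exclusion
#' `|j - j'| > min_sep` (Theiler window), ties broken towards the smaller
#' index.  Rows with no admissible neighbor are returned as `NA` and are
#' skipped by [divergence_curve()].
#'
#' @param traj an `mc_traj` matrix from [embed_series()].
#' @param p positive norm order; the minimisation itself depends on `p`.
#' @param min_sep temporal exclusion in samples (`>= 0`).
#'
#' @return A list of class `mc_neighbors` with integer `index`, numeric
#'   `dist`, and the `p`/`min_sep` used.
#' @examples
#' tr <- embed_series(c(0, 1, 4, 9, 16, 25), m = 2, J = 1)
#' nearest_neighbors(tr, p = 2, min_sep = 0)$index
#' @export
nearest_neighbors <- function(traj, p, min_sep) {
  stopifnot(is.matrix(traj))
  check_p(p)
  min_sep <- as.integer(min_sep)
  if (min_sep < 0L) stop("'min_sep' must be non-negative", call. = FALSE)
  res <- nn_search_cpp(unclass(traj), p, min_sep)
  if (all(is.na(res$index)))
    stop("no admissible neighbor pairs: min_sep = ", min_sep,
         " excludes every candidate for all ", nrow(traj), " rows",
         call. = FALSE)
  structure(list(index = res$index, dist = res$dist, p = p,
                 min_sep = min_sep),
            class = "mc_neighbors")
}

#' Average log-divergence curve of nearest-neighbor pairs
#'
#' Tracks each pair (trajectory point, its nearest neighbor) forward in
#' time and averages the log of their p-norm separation after `i` steps,
#' \eqn{y_p(i) = \langle \ln d_{j}^{p}(i) \rangle / \Delta t}.  For a
#' chaotic signal the curve rises linearly at rate GLLE(p) before
#' saturating at the attractor size.  Pairs whose indices run off the end
#' of the matrix, and pairs at exactly zero separation, are excluded from
#' the average at that step.
#'
#' @param traj an `mc_traj` matrix.
#' @param neighbors an `mc_neighbors` from [nearest_neighbors()], computed
#'   with the same `p`.
#' @param p positive norm order.
#' @param k_max number of forward steps tracked.
#' @param dt sampling period in seconds; defaults to the trajectory's.
#'
#' @return A data frame of class `mc_divergence` with columns `step`,
#'   `time_s`, `y_p` (log-distance per unit time) and `n_valid`.
#' @examples
#' s <- simulate_system("logistic", n_samples = 500, seed = 1)
#' tr <- embed_series(s, m = 2, J = 1)
#' nb <- nearest_neighbors(tr, p = 2, min_sep = 4)
#' head(divergence_curve(tr, nb, p = 2, k_max = 20))
#' @export
divergence_curve <- function(traj, neighbors, p, k_max, dt = NULL) {
  stopifnot(is.matrix(traj), inherits(neighbors, "mc_neighbors"))
  check_p(p)
  if (!isTRUE(all.equal(neighbors$p, p)))
    stop("'neighbors' were computed at p = ", neighbors$p,
         ", not at the requested p = ", p, call. = FALSE)
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("'k_max' must be at least 2", call. = FALSE)
  if (is.null(dt)) dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- 1
  k_max <- min(k_max, nrow(traj) - 1L)
  res <- div_curve_cpp(unclass(traj), neighbors$index, p, k_max)
  if (res$n_valid[1L] == 0L)
    stop("degenerate series: no neighbor pair has positive separation ",
         "at step 0", call. = FALSE)
  out <- data.frame(step = 0:k_max,
                    time_s = (0:k_max) * dt,
                    y_p = res$mean_log / dt,
                    n_valid = res$n_valid)
  structure(out, p = p, dt = dt,
            class = c("mc_divergence", "data.frame"))
}

# slope and r^2 of y over x by least squares; r^2 is NA for a flat response
ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  c(slope = slope, r2 = r2)
}

# Automatic fit-window selection: the initial divergence region, taken as
# the steps from 0 until the mean log-separation has climbed a fraction
# frac_sat of its total observed rise.  Fitting only this pre-saturation
# rise emulates the usual practice of fitting the initial linear region of
# the curve before it bends towards the attractor-size plateau, and is
# robust on noisy curves whose late stretches are smooth but flat.
select_fit_window <- function(curve, frac_sat = 0.5, min_len = 10L) {
  usable <- which(is.finite(curve$y_p) & curve$n_valid > 0L)
  if (length(usable) < max(3L, min_len))
    stop("too few valid divergence steps (", length(usable),
         ") for a fit window of length ", min_len, call. = FALSE)
  y <- curve$y_p[usable]
  steps <- curve$step[usable]
  rise <- max(y) - y[1L]
  if (rise <= 0) return(c(steps[1L], steps[min(length(steps), min_len)]))
  i_h <- which(y - y[1L] >= frac_sat * rise)[1L]
  i_h <- max(i_h, min(min_len + 1L, length(steps)))
  c(steps[1L], steps[i_h])
}

#' Fit the generalized largest Lyapunov exponent from a divergence curve
#'
#' Least-squares slope of the average log-separation versus time over a
#' window of the initial linear region, in units of 1/s.  When `window` is
#' `NULL` the window runs from step 0 to the step where the curve has
#' climbed `frac_sat` (default half) of its total observed rise — the
#' pre-saturation region, before bending towards the attractor-size
#' plateau distorts the slope.
#'
#' @param curve an `mc_divergence` from [divergence_curve()].
#' @param window integer pair `c(i_lo, i_hi)` of step indices, or `NULL`
#'   for automatic selection.
#' @param min_len minimum number of usable steps in the fitted window.
#' @param frac_sat fraction of the curve's total rise covered by the
#'   automatic window.
#'
#' @return A list of class `mc_glle` with `p`, `glle` (1/s), `fit_window`,
#'   `fit_r2`.
#' @examples
#' s <- simulate_system("logistic", n_samples = 2000, seed = 1)
#' tr <- embed_series(s, m = 2, J = 1)
#' nb <- nearest_neighbors(tr, p = 2, min_sep = 4)
#' cv <- divergence_curve(tr, nb, p = 2, k_max = 100)
#' fit_glle(cv)$glle  # close to ln 2
#' @export
fit_glle <- function(curve, window = NULL, min_len = 10L, frac_sat = 0.5) {
  stopifnot(inherits(curve, "mc_divergence"))
  dt <- attr(curve, "dt")
  if (is.null(window)) {
    window <- select_fit_window(curve, frac_sat = frac_sat,
                                min_len = min_len)
  } else {
    window <- as.integer(window)
    if (length(window) != 2L || window[1L] >= window[2L])
      stop("'window' must be c(i_lo, i_hi) with i_lo < i_hi", call. = FALSE)
  }
  rows <- curve$step >= window[1L] & curve$step <= window[2L] &
    is.finite(curve$y_p) & curve$n_valid > 0L
  if (sum(rows) < 3L)
    stop("fit window [", window[1L], ", ", window[2L],
         "] contains fewer than 3 valid steps", call. = FALSE)
  # slope of <ln d(i)> against i * dt gives the exponent in 1/s
  f <- ls_slope(curve$time_s[rows], curve$y_p[rows] * dt)
  structure(list(p = attr(curve, "p"), glle = unname(f["slope"]),
                 fit_window = window, fit_r2 = unname(f["r2"])),
            class = "mc_glle")
}

#' @export
print.mc_glle <- function(x, ...) {
  cat(sprintf("<mc_glle> p = %g: GLLE = %.4f 1/s (window %d..%d, r2 = %.3f)\n",
              x$p, x$glle, x$fit_window[1], x$fit_window[2], x$fit_r2))
  invisible(x)
}

#' Default p-norm grids
#'
#' `"benchmark"` is the 12-point grid \{0.1, 0.5, 1, 2, ..., 10\} used for
#' the simulated chaotic systems; `"rr"` is the 7-point grid
#' \{0.1, 0.5, 1, 2, 3, 4, 5\} appropriate for R-R interval series, where
#' higher orders lose discriminative content.
#'
#' @param type `"benchmark"` or `"rr"`.
#' @return Numeric vector of p-norm orders.
#' @examples
#' default_p_grid("rr")
#' @export
default_p_grid <- function(type = c("benchmark", "rr")) {
  switch(match.arg(type),
         benchmark = c(0.1, 0.5, 1:10),
         rr = c(0.1, 0.5, 1:5))
}

#' Spectrum of generalized largest Lyapunov exponents
#'
#' Runs the full multi-chaotic pipeline for every order in `p_grid`:
#' delay embedding, p-norm nearest-neighbor search (neighbors are
#' recomputed for each `p`, since the minimising neighbor depends on the
#' norm), divergence tracking, and a linear fit of the initial divergence
#' region.  The spectrum width \eqn{\Delta W} — max minus min GLLE over the
#' grid — quantifies the degree of multi-chaos: near zero for mono-chaotic
#' signals such as the Rossler attractor, positive when small- and
#' large-fluctuation components diverge at different rates.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param params an [embedding_params]; `NULL` estimates them via
#'   [estimate_embedding()].
#' @param p_grid ascending vector of positive norm orders (values at or
#'   below 0.05 are rejected as numerically unstable).
#' @param k_max forward steps tracked; default 100 when `dt >= 1`
#'   (maps, inter-beat series) and 500 for finely sampled flows.
#' @param min_sep temporal exclusion for the neighbor search; default the
#'   series' mean period from [mean_period()].
#' @param fit_window `NULL` for per-p automatic selection, or a fixed
#'   `c(i_lo, i_hi)` applied to every order.
#' @param delay_method delay estimator used when `params` is `NULL`.
#' @param m_max largest dimension probed by Cao's method when `params` is
#'   `NULL`.
#' @param keep_curves retain the divergence curves in the result.
#'
#' @return A data frame of class `mc_spectrum` with columns `p`, `glle`,
#'   `fit_lo`, `fit_hi`, `r2`; attributes `width` (\eqn{\Delta W}),
#'   `params`, `min_sep`, `k_max` and (optionally) `curves`.
#' @examples
#' s <- simulate_system("logistic", n_samples = 2000, seed = 1)
#' sp <- glle_spectrum(s, embedding_params(2, 1), p_grid = c(0.5, 2, 6))
#' spectrum_width(sp)
#' @export
glle_spectrum <- function(ts, params = NULL,
                          p_grid = default_p_grid("benchmark"),
                          k_max = NULL, min_sep = NULL, fit_window = NULL,
                          delay_method = "acf", m_max = 10L,
                          keep_curves = FALSE) {
  ts <- as_mc_series(ts)
  if (length(p_grid) < 1L) stop("'p_grid' is empty", call. = FALSE)
  if (is.unsorted(p_grid, strictly = TRUE))
    stop("'p_grid' must be strictly ascending", call. = FALSE)
  check_p(p_grid)
  if (is.null(params))
    params <- estimate_embedding(ts, delay_method = delay_method,
                                 m_max = m_max)
  traj <- embed_series(ts, params)
  M <- nrow(traj)
  if (is.null(min_sep)) min_sep <- ceiling(mean_period(ts))
  min_sep <- min(as.integer(min_sep), (M - 2L) %/% 2L)
  if (is.null(k_max)) k_max <- if (ts$dt >= 1) 100L else 500L
  k_max <- min(as.integer(k_max), M - 1L)

  fits <- vector("list", length(p_grid))
  curves <- if (keep_curves) vector("list", length(p_grid)) else NULL
  for (i in seq_along(p_grid)) {
    p <- p_grid[i]
    fits[[i]] <- tryCatch({
      nb <- nearest_neighbors(traj, p = p, min_sep = min_sep)
      cv <- divergence_curve(traj, nb, p = p, k_max = k_max, dt = ts$dt)
      if (keep_curves) curves[[i]] <- cv
      fit_glle(cv, window = fit_window)
    }, error = function(e) {
      stop(sprintf("GLLE estimation failed at p = %g: %s", p,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out <- data.frame(p = p_grid,
                    glle = vapply(fits, `[[`, numeric(1), "glle"),
                    fit_lo = vapply(fits, function(f) f$fit_window[1L],
                                    numeric(1)),
                    fit_hi = vapply(fits, function(f) f$fit_window[2L],
                                    numeric(1)),
                    r2 = vapply(fits, `[[`, numeric(1), "fit_r2"))
  structure(out,
            width = max(out$glle) - min(out$glle),
            params = params, min_sep = min_sep, k_max = k_max,
            dt = ts$dt, curves = curves,
            class = c("mc_spectrum", "data.frame"))
}

#' Width of a GLLE spectrum
#'
#' \eqn{\Delta W = \max_p GLLE(p) - \min_p GLLE(p)}; always non-negative,
#' and zero exactly when the spectrum is flat (mono-chaotic behavior).
#'
#' @param spectrum an `mc_spectrum` from [glle_spectrum()].
#' @return Non-negative scalar.
#' @examples
#' s <- simulate_system("logistic", n_samples = 2000, seed = 1)
#' sp <- glle_spectrum(s, embedding_params(2, 1), p_grid = c(0.5, 2, 6))
#' spectrum_width(sp)
#' @export
spectrum_width <- function(spectrum) {
  stopifnot(inherits(spectrum, "mc_spectrum"))
  if (nrow(spectrum) < 1L) stop("empty spectrum", call. = FALSE)
  max(spectrum$glle) - min(spectrum$glle)
}

#' @export
print.mc_spectrum <- function(x, ...) {
  cat(sprintf("<mc_spectrum> %d orders, m = %d, J = %d, delta_w = %.4f\n",
              nrow(x), attr(x, "params")$m, attr(x, "params")$J,
              attr(x, "width")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
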