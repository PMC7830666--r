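#' Grassberger-Procaccia correlation sum
#'
#' \eqn{C(r)}: the fraction of trajectory-point pairs, excluding pairs
#' closer in time than the Theiler window, whose Euclidean distance is
#' below `r`.  Monotone non-decreasing in `r` and bounded in `[0, 1]`.
#'
#' @param traj an `mc_traj` matrix from [embed_series()] (`M >= 10` rows).
#' @param radii ascending vector of positive radii (signal units).
#' @param theiler temporal exclusion in samples: pairs with
#'   `|j - j'| <= theiler` are ignored.
#'
#' @return A data frame of class `mc_corrsum` with columns `r` and `c_r`,
#'   attribute `n_pairs`.
#' @examples
#' tr <- embed_series(sin(1:100), m = 2, J = 1)
#' correlation_sum(tr, radii = c(0.1, 0.5, 1, 2, 3), theiler = 1)
#' @export
correlation_sum <- function(traj, radii, theiler = 0L) {
  stopifnot(is.matrix(traj))
  if (nrow(traj) < 10L) stop("need at least 10 trajectory points",
                             call. = FALSE)
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0))
    stop("'radii' must be positive and strictly ascending", call. = FALSE)
  theiler <- as.integer(theiler)
  res <- corr_sum_cpp(unclass(traj), as.numeric(radii), theiler)
  if (res$n_pairs == 0)
    stop("theiler = ", theiler, " excludes every pair", call. = FALSE)
  structure(data.frame(r = as.numeric(radii), c_r = res$c_r),
            n_pairs = res$n_pairs,
            class = c("mc_corrsum", "data.frame"))
}

# log-spaced radii between the 1st and 50th percentile of pairwise
# distances, estimated on an evenly strided row subsample
gp_radii <- function(traj, n_radii = 30L, n_ref = 1000L) {
  M <- nrow(traj)
  rows <- if (M > n_ref) round(seq(1L, M, length.out = n_ref)) else seq_len(M)
  d <- dist(traj[rows, , drop = FALSE])
  d <- d[d > 0]
  if (!length(d)) stop("degenerate trajectory: all pairwise distances zero",
                       call. = FALSE)
  q <- quantile(d, c(0.01, 0.50), names = FALSE)
  if (q[1] <= 0) q[1] <- min(d)
  exp(seq(log(q[1]), log(q[2]), length.out = n_radii))
}

#' Correlation dimension D2
#'
#' Estimates D2 as the least-squares slope of \eqn{\ln C(r)} versus
#' \eqn{\ln r} over an automatically selected scaling window: the
#' contiguous stretch of radii spanning at least half a decade with the
#' highest \eqn{r^2}.  D2 increases with the level of a random component
#' superimposed on deterministic dynamics, which is what makes it a useful
#' companion statistic to the GLLE spectrum width.
#'
#' @param ts an [mc_series] or numeric vector (length `>= 500`).
#' @param params an [embedding_params].
#' @param theiler temporal exclusion; default the series' mean period.
#' @param n_radii number of log-spaced radii (default 30, between the 1st
#'   and 50th percentile of pairwise distances).
#' @param r2_min windows below this goodness of fit mark the estimate
#'   low-confidence (default 0.98).
#'
#' @return A list of class `mc_d2` with `d2`, `scaling_window`, `r2`,
#'   `low_confidence` and the full `curve`.
#' @examples
#' s <- mc_series(runif(600))
#' estimate_d2(s, embedding_params(1, 1))$d2  # about 1
#' @export
estimate_d2 <- function(ts, params, theiler = NULL, n_radii = 30L,
                        r2_min = 0.98) {
  ts <- as_mc_series(ts)
  if (length(ts$values) < 500L)
    stop("need at least 500 samples for a D2 estimate", call. = FALSE)
  if (sd(ts$values) == 0)
    stop("correlation dimension undefined for a constant series",
         call. = FALSE)
  traj <- embed_series(ts, params)
  if (is.null(theiler)) theiler <- ceiling(mean_period(ts))
  radii <- gp_radii(traj, n_radii = n_radii)
  cs <- correlation_sum(traj, radii, theiler = theiler)
  ok <- cs$c_r > 0
  lr <- log(cs$r[ok])
  lc <- log(cs$c_r[ok])
  if (sum(ok) < 5L)
    stop("correlation sum is empty over the probed radii", call. = FALSE)
  # contiguous window spanning >= half a decade of r with maximal r^2
  half_decade <- log(10) / 2
  best <- NULL; best_r2 <- -Inf
  n <- length(lr)
  for (lo in seq_len(n - 4L)) {
    for (hi in seq(lo + 4L, n)) {
      if (lr[hi] - lr[lo] < half_decade) next
      f <- ls_slope(lr[lo:hi], lc[lo:hi])
      if (is.finite(f["r2"]) && f["r2"] > best_r2) {
        best_r2 <- f["r2"]; best <- c(lo, hi)
      }
    }
  }
  if (is.null(best)) { best <- c(1L, n); best_r2 <- NA_real_ }
  f <- ls_slope(lr[best[1]:best[2]], lc[best[1]:best[2]])
  low_conf <- !is.finite(best_r2) || best_r2 < r2_min
  if (low_conf)
    warning("no scaling window reached r2 >= ", r2_min,
            "; D2 estimate is low-confidence", call. = FALSE)
  structure(list(d2 = unname(f["slope"]),
                 scaling_window = c(r_lo = exp(lr[best[1]]),
                                    r_hi = exp(lr[best[2]])),
                 r2 = unname(f["r2"]),
                 low_confidence = low_conf,
                 curve = cs),
            class = "mc_d2")
}

#' @export
print.mc_d2 <- function(x, ...) {
  cat(sprintf("<mc_d2> D2 = %.3f (r in [%.3g, %.3g], r2 = %.4f%s)\n",
              x$d2, x$scaling_window[1], x$scaling_window[2], x$r2,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}
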