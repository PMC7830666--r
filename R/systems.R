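#' Benchmark chaotic system specification
#'
#' Bundles the name, parameters, sampling period, transient length, kept
#' length and seed of one of the four benchmark systems used to validate the
#' GLLE estimator: the logistic map, the Henon map, and the Lorenz and
#' Rossler flows.  Parameters default to the canonical chaotic settings
#' (logistic \eqn{\mu = 4}; Henon \eqn{a = 1.4, b = 0.3}; Lorenz
#' \eqn{\sigma = 10, R = 28, b = 8/3} at \eqn{\Delta t = 0.01} s; Rossler
#' \eqn{a = 0.15, b = 0.2, c = 10} at \eqn{\Delta t = 0.1} s).
#'
#' @param name one of `"logistic"`, `"henon"`, `"lorenz"`, `"rossler"`.
#' @param params named list overriding the default constants.
#' @param dt sampling period in seconds; defaults to the canonical step.
#' @param n_transient samples discarded before recording (default 1000 for
#'   maps, 10000 for flows, reaching the attractor before sampling).
#' @param n_samples samples kept (default 5000).
#' @param seed integer seed controlling the initial condition, or `NULL`.
#'
#' @return A `system_spec` list.
#' @examples
#' sp <- system_spec("lorenz", n_samples = 1000)
#' sp$params$sigma
#' @export
system_spec <- function(name = c("logistic", "henon", "lorenz", "rossler"),
                        params = list(), dt = NULL, n_transient = NULL,
                        n_samples = 5000, seed = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    logistic = list(params = list(mu = 4.0), dt = 1, n_transient = 1000L),
    henon    = list(params = list(a = 1.4, b = 0.3), dt = 1,
                    n_transient = 1000L),
    lorenz   = list(params = list(sigma = 10.0, R = 28.0, b = 8 / 3),
                    dt = 0.01, n_transient = 10000L),
    rossler  = list(params = list(a = 0.15, b = 0.20, c = 10.0),
                    dt = 0.1, n_transient = 10000L))
  p <- utils::modifyList(defaults$params, as.list(params))
  if (!all(vapply(p, function(v) is.numeric(v) && is.finite(v), logical(1))))
    stop("system parameters must be finite numbers", call. = FALSE)
  dt <- if (is.null(dt)) defaults$dt else dt
  n_transient <- as.integer(
    if (is.null(n_transient)) defaults$n_transient else n_transient)
  n_samples <- as.integer(n_samples)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (n_samples < 100L) stop("'n_samples' must be at least 100", call. = FALSE)
  if (n_transient < 0L) stop("'n_transient' must be non-negative", call. = FALSE)
  structure(list(name = name, params = p, dt = dt, n_transient = n_transient,
                 n_samples = n_samples, seed = seed),
            class = "system_spec")
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = leave the
# global stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Iterate the logistic map
#'
#' \eqn{x_{i+1} = \mu x_i (1 - x_i)}.  At \eqn{\mu = 4} the map is chaotic
#' on \eqn{[0, 1]} with largest Lyapunov exponent \eqn{\ln 2 \approx 0.69}.
#'
#' @param x0 initial condition, strictly inside `(0, 1)`.
#' @param mu growth parameter (default 4).
#' @param n number of iterates to append after `x0`.
#'
#' @return An [mc_series] of length `n + 1` with `dt = 1` s.
#' @examples
#' iterate_logistic(0.1, 4, 2)$values  # 0.1 0.36 0.9216
#' @export
iterate_logistic <- function(x0, mu = 4.0, n) {
  if (!is.numeric(mu) || !is.finite(mu))
    stop("'mu' must be a finite number", call. = FALSE)
  if (!is.numeric(x0) || !is.finite(x0) || x0 <= 0 || x0 >= 1)
    stop("'x0' must lie strictly inside (0, 1)", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  x <- numeric(n + 1L)
  x[1L] <- x0
  for (i in seq_len(n)) x[i + 1L] <- mu * x[i] * (1 - x[i])
  mc_series(x, dt = 1, meta = list(system = "logistic", mu = mu))
}

#' Iterate the Henon map
#'
#' \eqn{x_{i+1} = 1 - a x_i^2 + y_i}, \eqn{y_{i+1} = b x_i}; the
#' x-coordinate sequence is returned.  Orbits escaping `|x| > 1e6` abort
#' with an error naming the step, catching non-attractor parameter choices.
#'
#' @param x0,y0 initial condition.
#' @param a,b map parameters (defaults 1.4, 0.3).
#' @param n number of iterates to append after `x0`.
#'
#' @return An [mc_series] of length `n + 1` with `dt = 1` s.
#' @examples
#' iterate_henon(0, 0, n = 2)$values  # 0 1 -0.4
#' @export
iterate_henon <- function(x0, y0, a = 1.4, b = 0.3, n) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  stopifnot(is.finite(x0), is.finite(y0), is.finite(a), is.finite(b))
  x <- numeric(n + 1L)
  x[1L] <- x0
  y <- y0
  for (i in seq_len(n)) {
    xn <- 1 - a * x[i]^2 + y
    y <- b * x[i]
    if (!is.finite(xn) || abs(xn) > 1e6)
      stop(sprintf("Henon orbit diverged at step %d", i), call. = FALSE)
    x[i + 1L] <- xn
  }
  mc_series(x, dt = 1, meta = list(system = "henon", a = a, b = b))
}

lorenz_deriv <- function(t, state, parms) {
  with(as.list(c(state, parms)), {
    list(c(sigma * (y - x), x * (R - z) - y, x * y - b * z))
  })
}

rossler_deriv <- function(t, state, parms) {
  with(as.list(c(state, parms)), {
    list(c(-y - z, x + a * y, b + z * (x - c)))
  })
}

#' Integrate the Lorenz or Rossler flow
#'
#' Solves the system's ODEs with fixed-step fourth-order Runge-Kutta at step
#' `spec$dt`, discards `spec$n_transient` steps, and returns the
#' x-coordinate series — the standard scalar observable for delay
#' reconstruction of these attractors.
#'
#' @param spec a [system_spec] naming `"lorenz"` or `"rossler"`.
#' @param state0 initial state `c(x, y, z)`; default `c(1, 1, 1)`.
#'
#' @return An [mc_series] of `spec$n_samples` x-values.
#' @examples
#' integrate_flow(system_spec("rossler", n_samples = 200, n_transient = 100))
#' @export
integrate_flow <- function(spec, state0 = c(x = 1, y = 1, z = 1)) {
  stopifnot(inherits(spec, "system_spec"))
  if (!spec$name %in% c("lorenz", "rossler"))
    stop("integrate_flow handles 'lorenz' and 'rossler' specs", call. = FALSE)
  deriv <- if (spec$name == "lorenz") lorenz_deriv else rossler_deriv
  n_steps <- spec$n_transient + spec$n_samples
  times <- seq(0, by = spec$dt, length.out = n_steps + 1L)
  sol <- deSolve::rk4(y = state0, times = times, func = deriv,
                      parms = spec$params)
  x <- sol[, "x"]
  if (!all(is.finite(x)))
    stop(sprintf("%s integration produced non-finite state", spec$name),
         call. = FALSE)
  keep <- x[(spec$n_transient + 1L):(spec$n_transient + spec$n_samples)]
  mc_series(keep, dt = spec$dt,
            meta = c(list(system = spec$name), spec$params))
}

#' Simulate a benchmark chaotic system
#'
#' Seed-controlled front end over [iterate_logistic], [iterate_henon] and
#' [integrate_flow].  Map initial conditions are drawn uniformly from
#' (0.05, 0.95) — away from unstable fixed points and the degenerate
#' \eqn{x_0 = 0.5} preimage of 0 — and flows start from (1, 1, 1); the
#' transient is discarded before `n_samples` points are kept.
#'
#' @param spec a [system_spec], or a system name forwarded to [system_spec].
#' @param ... passed to [system_spec] when `spec` is a name.
#'
#' @return An [mc_series] of `n_samples` points.
#' @examples
#' s <- simulate_system("logistic", n_samples = 500, seed = 1)
#' range(s$values)
#' @export
simulate_system <- function(spec, ...) {
  if (is.character(spec)) spec <- system_spec(spec, ...)
  stopifnot(inherits(spec, "system_spec"))
  with_seed(spec$seed, {
    out <- switch(spec$name,
      logistic = {
        n <- spec$n_transient + spec$n_samples
        s <- iterate_logistic(runif(1, 0.05, 0.95), spec$params$mu, n)
        mc_series(tail(s$values, spec$n_samples), dt = spec$dt, meta = s$meta)
      },
      henon = {
        n <- spec$n_transient + spec$n_samples
        s <- iterate_henon(runif(1, 0.05, 0.95), 0, spec$params$a,
                           spec$params$b, n)
        mc_series(tail(s$values, spec$n_samples), dt = spec$dt, meta = s$meta)
      },
      integrate_flow(spec))
    out$meta$seed <- spec$seed
    out
  })
}

#' Add Gaussian observational noise to a series
#'
#' Adds i.i.d. zero-mean Gaussian draws to every sample, emulating a random
#' measurement component superimposed on deterministic dynamics.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param sd standard deviation of the noise (`>= 0`; 0 returns the input
#'   unchanged).
#' @param seed optional integer seed; identical seeds give identical output.
#'
#' @return An [mc_series] of the same length and `dt`.
#' @examples
#' s <- simulate_system("logistic", n_samples = 500, seed = 1)
#' noisy <- add_noise(s, sd = 0.05, seed = 2)
#' @export
add_noise <- function(ts, sd, seed = NULL) {
  ts <- as_mc_series(ts)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  if (sd == 0) return(ts)
  noise <- with_seed(seed, rnorm(length(ts$values), mean = 0, sd = sd))
  out <- ts
  out$values <- ts$values + noise
  out$meta$noise_sd <- sd
  out
}
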