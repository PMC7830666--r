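#' Scalar time series with a sampling period
#'
#' Lightweight container for an evenly sampled scalar signal: an ordered
#' vector of finite real values plus the sampling period `dt` in seconds.
#' All estimators in the package accept either an `mc_series` or a bare
#' numeric vector (then taken to have `dt = 1`).
#'
#' @param values numeric vector of samples; must be finite and non-empty.
#' @param dt sampling period in seconds (`> 0`).
#' @param meta named list of free-form provenance labels.
#'
#' @return An object of class `mc_series`.
#' @examples
#' s <- mc_series(sin(seq(0, 20, by = 0.1)), dt = 0.1)
#' length(s$values)
#' @export
mc_series <- function(values, dt = 1, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one sample", call. = FALSE)
  if (!all(is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  structure(list(values = values, dt = as.numeric(dt), meta = meta),
            class = "mc_series")
}

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("<mc_series> %d samples, dt = %g s\n", length(x$values), x$dt))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.mc_series <- function(x) length(x$values)

# Coerce numeric vectors on the way into estimators.
as_mc_series <- function(x, dt = 1) {
  if (inherits(x, "mc_series")) return(x)
  if (is.numeric(x)) return(mc_series(x, dt = dt))
  stop("expected an 'mc_series' or a numeric vector", call. = FALSE)
}
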