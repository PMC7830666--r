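#' Read an R-R interval series from a plain-text file
#'
#' One interval per line; `#`-prefixed lines are comments.  Millisecond
#' inputs are converted to seconds.  Non-numeric or non-positive lines are
#' rejected with their 1-based line numbers; more than 1% rejected lines
#' (or an empty file) is a format error.
#'
#' @param path path to the text file.
#' @param units `"s"` or `"ms"`.
#' @param subject subject identifier; default the file name without
#'   extension.
#' @param group group label (`"hs"`, `"chf"`, `"af"` or `"unknown"`).
#'
#' @return An `rr_record`: list with `subject`, `group`, `series`
#'   (an [mc_series] in seconds, `dt = 1` beat), `path`, `n_rejected`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0.8", "0.82", "0.79"), f)
#' read_rr(f)$series$values
#' @export
read_rr <- function(path, units = c("s", "ms"), subject = NULL,
                    group = "unknown") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx)) stop("no data lines in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[data_idx])))
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    bad_lines <- data_idx[bad]
    if (mean(bad) > 0.01)
      stop(sprintf("%s: %d invalid interval line(s) (> 1%%), e.g. line %d",
                   path, sum(bad), bad_lines[1L]), call. = FALSE)
    warning(sprintf("%s: dropped %d invalid line(s): %s", path, sum(bad),
                    paste(head(bad_lines, 5L), collapse = ", ")),
            call. = FALSE)
    vals <- vals[!bad]
  }
  if (units == "ms") vals <- vals / 1000
  if (is.null(subject)) subject <- sub("\\.[^.]*$", "", basename(path))
  structure(list(subject = subject,
                 group = match.arg(group, c("hs", "chf", "af", "unknown")),
                 series = mc_series(vals, dt = 1,
                                    meta = list(kind = "rr", units = "s")),
                 path = path, n_rejected = sum(bad)),
            class = "rr_record")
}

#' Write a series as plain text
#'
#' One sample per line, preceded by `#` header lines carrying `dt` and any
#' metadata; the format [read_series()] and the `simulate` CLI subcommand
#' use.  Values are written at full double precision so a write/read
#' round-trip is exact.
#'
#' @param ts an [mc_series] or numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_series(mc_series(c(0.8, 0.82), dt = 1), f)
#' read_series(f)$values
#' @export
write_series <- function(ts, path) {
  ts <- as_mc_series(ts)
  hdr <- c(sprintf("# dt=%.17g", ts$dt),
           vapply(names(ts$meta),
                  function(k) sprintf("# %s=%s", k,
                                      format(ts$meta[[k]], digits = 17)),
                  character(1)))
  writeLines(c(hdr, sprintf("%.17g", ts$values)), path)
  invisible(path)
}

#' Read a series written by [write_series()]
#'
#' @param path input path.
#' @return An [mc_series]; `dt` and metadata are recovered from the `#`
#'   header lines.
#' @export
read_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  vals <- as.numeric(lines[!grepl("^\\s*(#|$)", lines)])
  meta <- list()
  dt <- 1
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) next
    if (kv[1L] == "dt") dt <- as.numeric(kv[2L])
    else meta[[kv[1L]]] <- type.convert(kv[2L], as.is = TRUE)
  }
  mc_series(vals, dt = dt, meta = meta)
}

#' Analysis configuration for the R-R pipeline
#'
#' Collects every knob of [run_pipeline()] so a run is reproducible from
#' its configuration alone.  Serialisable to a flat text file with
#' [write_config()] / [read_config()].
#'
#' @param delay_method delay estimator (default `"ci"`, the cheap
#'   correlation-integral criterion).
#' @param m_max largest dimension probed by Cao's method.
#' @param p_grid p-norm grid for the spectrum (default the 7-point R-R
#'   grid).
#' @param k_max divergence steps tracked (`NULL` = 100 for beat-indexed
#'   series).
#' @param min_sep Theiler window (`NULL` = mean period).
#' @param fit_window fixed fit window, or `NULL` for automatic.
#' @param window_length analysis window: the first this-many intervals of
#'   each record are analysed (default 5000, about one hour of beats).
#' @param window_offset 0-based offset of the analysis window into the
#'   record.
#' @param seed integer seed recorded with the run.
#' @param out_dir directory for per-subject artifacts, or `NULL` to skip
#'   writing.
#'
#' @return A validated list of class `run_config`.
#' @examples
#' run_config(window_length = 1000)
#' @export
run_config <- function(delay_method = "ci", m_max = 10L,
                       p_grid = default_p_grid("rr"), k_max = NULL,
                       min_sep = NULL, fit_window = NULL,
                       window_length = 5000L, window_offset = 0L,
                       seed = NULL, out_dir = NULL) {
  delay_method <- match.arg(delay_method, c("ci", "acf", "mi"))
  check_p(p_grid)
  window_length <- as.integer(window_length)
  if (window_length < 200L)
    stop("'window_length' must be at least 200", call. = FALSE)
  structure(list(delay_method = delay_method, m_max = as.integer(m_max),
                 p_grid = as.numeric(p_grid), k_max = k_max,
                 min_sep = min_sep, fit_window = fit_window,
                 window_length = window_length,
                 window_offset = as.integer(window_offset),
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path for the flat `key: value` serialisation.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.null(v)) return("")
    paste(format(v, digits = 17), collapse = ",")
  }
  writeLines(vapply(names(config),
                    function(k) sprintf("%s: %s", k, fmt(config[[k]])),
                    character(1)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([a-z_]+):\\s*(.*)$", lines))
  vals <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- m[2L]; raw <- trimws(m[3L])
    if (raw == "") { vals[key] <- list(NULL); next }
    parts <- strsplit(raw, ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(parts))
    vals[[key]] <- if (all(is.finite(num))) num else raw
  }
  do.call(run_config, vals)
}

analysis_window <- function(record, config) {
  x <- record$series$values
  n <- length(x)
  off <- config$window_offset
  want <- config$window_length
  if (n - off < want) {
    warning(sprintf("%s: only %d intervals available after offset %d; %s",
                    record$subject, n - off, off,
                    "analysing the full available length"), call. = FALSE)
    want <- n - off
  }
  mc_series(x[(off + 1L):(off + want)], dt = record$series$dt,
            meta = record$series$meta)
}

#' Run the full multi-chaotic analysis pipeline over R-R records
#'
#' For each record: truncate to the analysis window, estimate delay and
#' Cao dimension, compute the GLLE spectrum over the R-R p-grid with its
#' width, the correlation dimension D2, the x100 features, and both
#' logistic model scores.  Per-subject failures are logged and skipped.
#'
#' @param config a [run_config].
#' @param inputs list of `rr_record` objects (see [read_rr()]), or of
#'   [mc_series] (then labelled `subject_1, ...`, group `"unknown"`).
#'
#' @return A list of class `mc_pipeline` with `features` (one row per
#'   subject: embedding, GLLE features, `delta_w`, `d2`, model
#'   probabilities and labels), `spectra` (per-subject `mc_spectrum`),
#'   `log` (character), and `failed` (subject ids).
#' @examples
#' rec <- list(structure(list(subject = "sim", group = "unknown",
#'                            series = simulate_system("logistic",
#'                              n_samples = 1200, seed = 1)),
#'             class = "rr_record"))
#' run_pipeline(run_config(window_length = 1000), rec)$features
#' @export
run_pipeline <- function(config, inputs) {
  stopifnot(inherits(config, "run_config"))
  if (!length(inputs)) stop("no inputs", call. = FALSE)
  inputs <- lapply(seq_along(inputs), function(i) {
    rec <- inputs[[i]]
    if (inherits(rec, "rr_record")) return(rec)
    structure(list(subject = paste0("subject_", i), group = "unknown",
                   series = as_mc_series(rec), path = NA_character_),
              class = "rr_record")
  })
  log_lines <- character(0)
  note <- function(stage, subject, msg) {
    line <- sprintf("[%s] %s: %s", stage, subject, msg)
    log_lines[[length(log_lines) + 1L]] <<- line
    line
  }

  rows <- list(); spectra <- list(); failed <- character(0)
  for (rec in inputs) {
    res <- tryCatch({
      ts <- analysis_window(rec, config)
      emb <- estimate_embedding(ts, delay_method = config$delay_method,
                                m_max = config$m_max)
      sp <- glle_spectrum(ts, params = emb, p_grid = config$p_grid,
                          k_max = config$k_max, min_sep = config$min_sep,
                          fit_window = config$fit_window)
      fv <- 100 * sp$glle
      names(fv) <- paste0("glle_", sub("\\.?0+$", "", format(sp$p)))
      d2 <- tryCatch(estimate_d2(ts, emb)$d2, error = function(e) NA_real_)
      s1 <- score(model1_scorer(), fv)
      s2 <- score(model2_scorer(), fv)
      note("glle", rec$subject,
           sprintf("m=%d J=%d delta_w=%.4f", emb$m, emb$J, attr(sp, "width")))
      list(row = data.frame(subject = rec$subject, group = rec$group,
                            n = length(ts$values), m = emb$m, J = emb$J,
                            as.list(fv),
                            delta_w = attr(sp, "width"), d2 = d2,
                            p_model1 = s1$probability, label_model1 = s1$label,
                            p_model2 = s2$probability, label_model2 = s2$label,
                            check.names = FALSE),
           spectrum = sp)
    }, error = function(e) {
      note("error", rec$subject, conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, rec$subject); next }
    rows[[rec$subject]] <- res$row
    spectra[[rec$subject]] <- res$spectrum
  }
  if (!length(rows))
    stop("pipeline failed for every input:\n",
         paste(log_lines, collapse = "\n"), call. = FALSE)
  features <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    write_config(config, file.path(config$out_dir, "config.txt"))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  structure(list(features = features, spectra = spectra, log = log_lines,
                 failed = failed, config = config),
            class = "mc_pipeline")
}

#' Median and quartile summary per group
#'
#' Median (Me) with first and third quartiles (linear-interpolation,
#' type-7 convention) of `glle_2`, `delta_w` and `d2` per group label.
#' Groups with fewer than 3 subjects are omitted with a warning.
#'
#' @param features the feature table from [run_pipeline()], or any data
#'   frame with a `group` column and the summarised columns.
#' @param vars columns to summarise.
#'
#' @return A data frame: one row per group and variable, columns `group`,
#'   `variable`, `n`, `me`, `q1`, `q3`.
#' @examples
#' df <- data.frame(group = rep("hs", 5), glle_2 = 1:5,
#'                  delta_w = 1:5, d2 = 1:5)
#' summarize_groups(df)
#' @export
summarize_groups <- function(features,
                             vars = c("glle_2", "delta_w", "d2")) {
  stopifnot("group" %in% names(features))
  vars <- intersect(vars, names(features))
  out <- list()
  for (g in unique(features$group)) {
    sub <- features[features$group == g, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warning("group '", g, "' has fewer than 3 subjects; omitted",
              call. = FALSE)
      next
    }
    for (v in vars) {
      x <- sub[[v]][is.finite(sub[[v]])]
      if (!length(x)) next
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(group = g, variable = v,
                                            n = length(x), me = q[2L],
                                            q1 = q[1L], q3 = q[3L])
    }
  }
  if (!length(out)) stop("no group with at least 3 subjects", call. = FALSE)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Serialise a logistic scorer as flat key-value text
#'
#' @param scorer an `mc_scorer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile()
#' write_scorer(model1_scorer(), f)
#' read_scorer(f)
#' @export
write_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "mc_scorer"))
  lines <- c(sprintf("intercept: %.17g", scorer$intercept),
             sprintf("threshold: %.17g", scorer$threshold),
             sprintf("positive: %s", scorer$positive),
             sprintf("negative: %s", scorer$negative),
             sprintf("coef %s: %.17g", names(scorer$coefficients),
                     scorer$coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get1 <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    trimws(sub("^[^:]+:", "", hit[1L]))
  }
  cf_lines <- grep("^coef ", lines, value = TRUE)
  m <- regmatches(cf_lines, regexec("^coef ([^:]+):\\s*(.*)$", cf_lines))
  cf <- vapply(m, function(x) as.numeric(x[3L]), numeric(1))
  names(cf) <- vapply(m, function(x) trimws(x[2L]), character(1))
  logistic_scorer(as.numeric(get1("intercept")), cf,
                  threshold = as.numeric(get1("threshold")),
                  positive = get1("positive"), negative = get1("negative"))
}
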