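# Descriptor time series (RMSD in nm, hydrogen-bond counts), their
# mean/SD summaries, plateau-onset detection, and the molecule-by-
# temperature comparison grid.

#' Construct a descriptor time series
#'
#' @param times frame times in nanoseconds, strictly increasing.
#' @param values descriptor values (RMSD in nm, or hydrogen-bond counts);
#'   RMSD values must be non-negative.
#' @param units unit tag, e.g. `"nm"` or `"count"`.
#' @param label free-text label.
#' @return an object of class `aptamer_series`.
#' @export
aptamer_series <- function(times, values, units = "nm", label = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (units == "nm" && any(values < 0))
    stop("RMSD values must be non-negative")
  structure(list(times = times, values = values, units = units,
                 label = label), class = "aptamer_series")
}

#' @export
print.aptamer_series <- function(x, ...) {
  cat("aptamer_series", if (nzchar(x$label)) paste0("'", x$label, "'"),
      ": ", length(x$times), " points, ", x$units,
      ", time ", min(x$times), "-", max(x$times), " ns\n", sep = "")
  invisible(x)
}

#' Write a series as two-column TSV
#'
#' Emits `time_ns<TAB>value` rows under a `#`-prefixed header.
#'
#' @param series an [aptamer_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "aptamer_series"))
  lines <- c(sprintf("# %s (%s)", series$label, series$units),
             "# time_ns\tvalue",
             sprintf("%.6g\t%.10g", series$times, series$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column TSV series written by [write_series]
#' @param path input path.
#' @param units,label metadata for the returned series (the TSV header
#'   comment is used for `label` when omitted).
#' @return an [aptamer_series].
#' @export
read_series <- function(path, units = NULL, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  times <- as.numeric(vapply(parts, `[`, character(1), 1L))
  vals <- as.numeric(vapply(parts, `[`, character(1), 2L))
  meta <- if (length(hdr)) sub("^# *", "", hdr[1]) else ""
  u <- units %||% if (grepl("\\(count\\)", meta)) "count" else "nm"
  aptamer_series(times, vals, units = u,
                 label = label %||% sub(" *\\(.*\\)$", "", meta))
}

#' Mean and standard deviation of a series
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the values with time >= `discard_before`, the aggregation used for
#' per-run summary tables.
#'
#' @param series an [aptamer_series].
#' @param discard_before discard frames earlier than this time (ns);
#'   default 0 keeps everything.
#' @return an object of class `series_summary` with fields `mean`, `sd`,
#'   `n`, `units`, `label`.
#' @examples
#' s <- aptamer_series(0:2, c(1, 2, 3))
#' summarize_series(s)  # mean 2, sd 1
#' @export
summarize_series <- function(series, discard_before = 0) {
  stopifnot(inherits(series, "aptamer_series"))
  keep <- series$times >= discard_before
  if (sum(keep) < 2)
    stop("fewer than 2 frames remain after discarding before ",
         discard_before, " ns")
  v <- series$values[keep]
  structure(list(mean = mean(v), sd = stats::sd(v), n = length(v),
                 units = series$units, label = series$label),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("series_summary '%s': mean %.4g, sd %.4g (%s, n = %d)\n",
              x$label, x$mean, x$sd, x$units, x$n))
  invisible(x)
}

#' Detect the onset of a stationary plateau in a series
#'
#' Finds the earliest time t such that every sliding window of width
#' `window` between t and the end of the series has least-squares slope
#' magnitude at most `slope_tol` and standard deviation at most
#' `fluctuation_tol`.  Such sustained low-slope, low-fluctuation regimes
#' are the usual practical reading of conformational stabilization in
#' RMSD profiles.
#'
#' @param series an [aptamer_series] spanning at least `2 * window`.
#' @param window window width in ns (default 20).
#' @param slope_tol maximum |slope| in units/ns (default 0.005, tuned for
#'   RMSD in nm).
#' @param fluctuation_tol maximum within-window SD in series units
#'   (default 0.1).
#' @return an object of class `plateau_result` with `onset_time` (ns, or
#'   `NA` when no plateau exists) and the parameters used.
#' @export
detect_plateau <- function(series, window = 20, slope_tol = 0.005,
                           fluctuation_tol = 0.1) {
  stopifnot(inherits(series, "aptamer_series"), window > 0)
  tt <- series$times; vv <- series$values
  span <- max(tt) - min(tt)
  if (span < 2 * window)
    stop("series spans ", span, " ns; need at least 2 * window = ",
         2 * window, " ns")
  n <- length(tt)
  # a window starting at index i covers [tt[i], tt[i] + window]
  ok <- rep(NA, n)  # NA: window does not fit
  for (i in seq_len(n)) {
    jmax <- tt <= tt[i] + window
    j <- which(jmax & seq_len(n) >= i)
    if (tt[i] + window > max(tt) + 1e-9) break
    if (length(j) < 2) next
    x <- tt[j]; y <- vv[j]
    slope <- stats::cov(x, y) / stats::var(x)
    if (abs(slope) <= slope_tol && stats::sd(y) <= fluctuation_tol)
      ok[i] <- TRUE
    else
      ok[i] <- FALSE
  }
  fits <- which(!is.na(ok))
  onset <- NA_real_
  if (length(fits)) {
    bad <- fits[!ok[fits]]
    first_all_good <- if (length(bad)) max(bad) + 1L else fits[1]
    if (first_all_good <= max(fits) && all(ok[fits[fits >= first_all_good]]))
      onset <- tt[first_all_good]
  }
  structure(list(onset_time = onset, window = window,
                 slope_tol = slope_tol, fluctuation_tol = fluctuation_tol),
            class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  if (is.na(x$onset_time))
    cat("plateau_result: no plateau",
        sprintf("(window %g ns, |slope| <= %g, sd <= %g)\n",
                x$window, x$slope_tol, x$fluctuation_tol))
  else
    cat(sprintf("plateau_result: onset %g ns (window %g ns, |slope| <= %g, sd <= %g)\n",
                x$onset_time, x$window, x$slope_tol, x$fluctuation_tol))
  invisible(x)
}

#' Comparison grid of run summaries
#'
#' Arranges hydrogen-bond and RMSD summaries of several runs (molecule x
#' temperature) into one row per run with columns `hb_mean`, `hb_sd`,
#' `rmsd_mean`, `rmsd_sd` -- the layout of per-run MD summary tables.
#' Series with units `"count"` populate the H-bond columns; `"nm"` the
#' RMSD columns.
#'
#' @param summaries list of [summarize_series] results.
#' @param labels run label per summary (e.g. `"A6 (300 K)"`); defaults to
#'   the summaries' own labels.  A (label, metric) pair may occur only
#'   once.
#' @return data frame, one row per label.
#' @export
compare_runs <- function(summaries, labels = NULL) {
  stopifnot(length(summaries) >= 1)
  if (is.null(labels))
    labels <- vapply(summaries, function(s) s$label, character(1))
  if (length(labels) != length(summaries))
    stop("one label per summary required")
  units <- vapply(summaries, function(s) s$units, character(1))
  if (!all(units %in% c("count", "nm")))
    stop("unit mismatch: expected 'count' (H-bonds) or 'nm' (RMSD), got ",
         paste(setdiff(units, c("count", "nm")), collapse = ", "))
  metric <- ifelse(units == "count", "hb", "rmsd")
  if (anyDuplicated(paste(labels, metric)))
    stop("duplicate label for the same metric: ",
         paste(labels[duplicated(paste(labels, metric))], collapse = ", "))
  out <- data.frame(label = unique(labels), hb_mean = NA_real_,
                    hb_sd = NA_real_, rmsd_mean = NA_real_,
                    rmsd_sd = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(summaries)) {
    i <- match(labels[k], out$label)
    if (metric[k] == "hb") {
      out$hb_mean[i] <- summaries[[k]]$mean
      out$hb_sd[i] <- summaries[[k]]$sd
    } else {
      out$rmsd_mean[i] <- summaries[[k]]$mean
      out$rmsd_sd[i] <- summaries[[k]]$sd
    }
  }
  out
}
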