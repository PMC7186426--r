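#' Classification series at 0.5-s spacing
#'
#' @param times segment times in seconds, uniformly spaced by 0.5 s
#' @param values workload classes in \{1, 2, 3\} (NA allowed for artifact
#'   gaps)
#' @return object of class \code{classification_series}
#' @export
classification_series <- function(times, values) {
  if (length(times) != length(values)) stop_dfhm("times/values length mismatch")
  if (length(times) > 1 && any(abs(diff(times) - 0.5) > 1e-9)) {
    stop_dfhm("classification series must be spaced by exactly 0.5 s")
  }
  values <- as.integer(values)
  if (!all(values[!is.na(values)] %in% 1:3)) {
    stop_dfhm("classification values must be in {1, 2, 3}")
  }
  structure(list(times = as.numeric(times), values = values),
            class = "classification_series")
}

#' @export
print.classification_series <- function(x, ...) {
  cat("<classification_series> ", length(x$values), " values @ 0.5 s",
      if (length(x$times)) paste0(" from t = ", x$times[1], " s"), "\n",
      sep = "")
  invisible(x)
}

#' DFHM workload index: 30-s moving average on a 0-100 scale
#'
#' At every classification time t from the 60th value onwards the index is
#' \deqn{(\sum_{i=t-59}^{t} c_i - 60) / 120 \times 100,} where the c_i are
#' the 60 class values (1/2/3) of the trailing 30-s window.  Subtracting the
#' minimum-possible window sum of 60 sets the all-low baseline to 0, and the
#' maximum adjusted sum of 120 (all high) maps to 100, so the index reads as
#' the percentage position between all-low and all-high workload within the
#' window.  The first 59 times (29.5 s) have no full window and are
#' undefined (NA), as is any window touching an NA class value.
#'
#' @param series a \code{classification_series} with at least 60 values
#' @return object of class \code{workload_index_series}: \code{times} and
#'   \code{values} in [0, 100] or NA
#' @export
workload_index <- function(series) {
  stopifnot(inherits(series, "classification_series"))
  n <- length(series$values)
  if (n < 60) stop_dfhm("need at least 60 classification values (30 s)")
  wsum <- stats::filter(series$values, rep(1, 60), sides = 1)
  idx <- (as.numeric(wsum) - 60) / 120 * 100
  structure(list(times = series$times, values = idx),
            class = "workload_index_series")
}

#' @export
print.workload_index_series <- function(x, ...) {
  def <- !is.na(x$values)
  cat("<workload_index_series> ", length(x$values), " samples, ",
      sum(def), " defined", sep = "")
  if (any(def)) {
    cat(", mean ", round(mean(x$values[def]), 1), ", range [",
        round(min(x$values[def]), 1), ", ", round(max(x$values[def]), 1), "]",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Mean workload index over a time slot
#'
#' Arithmetic mean of the defined index values with start <= t < start +
#' duration (half-open).  Used for the first-5-min reliability means and the
#' 2.5-min post-request slots.
#'
#' @param idx a \code{workload_index_series}
#' @param start slot start in seconds
#' @param duration slot duration in seconds
#' @return mean index over the slot
#' @export
slot_mean <- function(idx, start, duration) {
  sel <- idx$times >= start & idx$times < start + duration & !is.na(idx$values)
  if (!any(sel)) stop_dfhm("no defined index values in slot [", start, ", ",
                           start + duration, ")")
  mean(idx$values[sel])
}

#' Export a workload index series as CSV
#'
#' Columns \code{time_s,index}; undefined values are written as empty
#' fields.
#'
#' @param idx a \code{workload_index_series}
#' @param path output path
#' @param comment optional comment line (e.g. a config hash) written with a
#'   leading \code{#}
#' @return \code{path}, invisibly
#' @export
write_index_csv <- function(idx, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("time_s,index", con)
  vals <- ifelse(is.na(idx$values), "", format(idx$values, digits = 10,
                                               trim = TRUE, scientific = FALSE))
  writeLines(paste(format(idx$times, trim = TRUE, scientific = FALSE),
                   vals, sep = ","), con)
  invisible(path)
}
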