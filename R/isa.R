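# Instantaneous self-assessment (ISA) workload-sensitivity analysis.
#
# Each subject rates workload on a 5-point scale every 5 minutes; a linear
# model of rating on traffic load (aircraft per hour) summarizes how strongly
# the subject's subjective workload follows the load manipulation.  The raw
# slope is made scale-free by normalizing both axes with their scale means,
# giving the sensitivity index s_a with normalized intercept s_b = 1 - s_a;
# a median split on s_a separates workload-sensitive from not-sensitive
# subjects.

#' Per-subject ordinary least squares of ISA rating on traffic load
#'
#' All ratings of one subject are pooled (across scenarios and rating time
#' points) and regressed on traffic load.
#'
#' @param records data frame with columns \code{rating} (1-5) and
#'   \code{traffic_load} (ac/h) for a single subject
#' @return list with \code{slope} (ISA per ac/h) and \code{intercept}
#' @export
fit_isa_line <- function(records) {
  if (length(unique(records$traffic_load)) < 2) {
    stop_dfhm("need ratings at >= 2 distinct traffic loads")
  }
  fit <- stats::lm(rating ~ traffic_load, data = records)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Normalized workload sensitivity from a fitted ISA line
#'
#' With load-scale mean \eqn{\bar L = (L_{max} + L_{min})/2} and ISA-scale
#' mean \eqn{\bar I = (\hat y(L_{max}) + \hat y(L_{min}))/2} taken from the
#' subject's own regression line, the sensitivity is
#' \eqn{s_a = b \bar L / \bar I} and the normalized intercept
#' \eqn{s_b = 1 - s_a} (exact by construction).
#'
#' @param slope,intercept fitted ISA line coefficients
#' @param loads traffic-load levels of the design; default
#'   \code{c(25, 35, 45, 55)} ac/h
#' @return list with \code{s_a} and \code{s_b}
#' @export
sensitivity_index <- function(slope, intercept, loads = c(25, 35, 45, 55)) {
  l_lo <- min(loads)
  l_hi <- max(loads)
  l_bar <- (l_hi + l_lo) / 2
  i_bar <- (intercept + slope * l_hi + intercept + slope * l_lo) / 2
  if (i_bar == 0) stop_dfhm("degenerate ISA line: scale mean is zero")
  s_a <- slope * l_bar / i_bar
  list(s_a = s_a, s_b = 1 - s_a)
}

#' Fit the workload-sensitivity index for a cohort
#'
#' Runs the per-subject regression and normalization for every subject in
#' the ISA table and clusters the cohort by the median of s_a: subjects at
#' or above the median are labelled \code{sensitive}, below it
#' \code{not_sensitive} (ties go to sensitive).
#'
#' @param records data frame with columns \code{subject}, \code{rating},
#'   \code{traffic_load} (extra columns such as scenario and time are
#'   ignored)
#' @param loads design load levels; default \code{c(25, 35, 45, 55)}
#' @return object of class \code{isa_sensitivity}: a list with
#'   \code{results} (data frame subject, slope, intercept, s_a, s_b,
#'   cluster) and \code{median_s_a}
#' @export
fit_isa_sensitivity <- function(records, loads = c(25, 35, 45, 55)) {
  subjects <- unique(records$subject)
  if (length(subjects) < 1) stop_dfhm("empty cohort")
  rows <- lapply(subjects, function(s) {
    line <- fit_isa_line(records[records$subject == s, , drop = FALSE])
    si <- sensitivity_index(line$slope, line$intercept, loads)
    data.frame(subject = s, slope = line$slope, intercept = line$intercept,
               s_a = si$s_a, s_b = si$s_b)
  })
  res <- do.call(rbind, rows)
  out <- structure(list(results = res, median_s_a = NA_real_, loads = loads),
                   class = "isa_sensitivity")
  cluster_by_median(out)
}

#' Median-split clustering on the sensitivity index
#'
#' @param x an \code{isa_sensitivity} object (>= 2 subjects for a meaningful
#'   split)
#' @return the object with \code{results$cluster} filled in and
#'   \code{median_s_a} set
#' @export
cluster_by_median <- function(x) {
  res <- x$results
  if (nrow(res) < 1) stop_dfhm("empty cohort")
  med <- stats::median(res$s_a)
  res$cluster <- ifelse(res$s_a >= med, "sensitive", "not_sensitive")
  x$results <- res
  x$median_s_a <- med
  x
}

#' @export
print.isa_sensitivity <- function(x, ...) {
  cat("<isa_sensitivity> ", nrow(x$results), " subjects, median s_a = ",
      round(x$median_s_a, 3), " (", sum(x$results$cluster == "sensitive"),
      " sensitive / ", sum(x$results$cluster == "not_sensitive"),
      " not sensitive)\n", sep = "")
  invisible(x)
}

#' @export
coef.isa_sensitivity <- function(object, ...) {
  stats::setNames(object$results$s_a, object$results$subject)
}

#' Read / write ISA tables and sensitivity results as CSV
#'
#' Input CSV columns: \code{subject,scenario,time_s,rating,traffic_load};
#' output columns: \code{subject,slope,intercept,s_a,s_b,cluster}.
#'
#' @param path CSV path
#' @param x an \code{isa_sensitivity}
#' @return \code{read_isa_csv} returns a data frame;
#'   \code{write_sensitivity_csv} returns \code{path} invisibly.
#' @export
read_isa_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("subject", "rating", "traffic_load")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) stop_dfhm("ISA CSV misses columns: ",
                                  paste(miss, collapse = ", "))
  df
}

#' @rdname read_isa_csv
#' @export
write_sensitivity_csv <- function(x, path) {
  utils::write.csv(x$results, path, row.names = FALSE)
  invisible(path)
}
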