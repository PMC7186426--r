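# Air-traffic-control performance metrics: route distance of arrival
# trajectories, wake-vortex loss-of-separation detection against ICAO-style
# minima, and paired Wilcoxon signed-rank comparison.

#' Construct an aircraft trajectory
#'
#' Planar terminal-area coordinates in nautical miles (x, y) plus altitude
#' in feet, sampled at strictly increasing times.
#'
#' @param id aircraft identifier
#' @param wake_class \code{"medium"} or \code{"heavy"}
#' @param samples data frame with columns \code{time} (s), \code{x},
#'   \code{y} (NM), \code{alt} (ft)
#' @param contact_time time of initial radio contact (s)
#' @param landing_time landing time (s); must exceed \code{contact_time} and
#'   both must lie within the sampled span
#' @return object of class \code{trajectory}
#' @export
trajectory <- function(id, wake_class, samples, contact_time, landing_time) {
  wake_class <- match.arg(wake_class, c("medium", "heavy"))
  samples <- as.data.frame(samples)
  stopifnot(all(c("time", "x", "y", "alt") %in% names(samples)))
  if (any(diff(samples$time) <= 0)) stop_dfhm("sample times must strictly increase")
  if (!(contact_time < landing_time)) stop_dfhm("contact_time must precede landing_time")
  structure(list(id = id, wake_class = wake_class, samples = samples,
                 contact_time = contact_time, landing_time = landing_time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$id, " (", x$wake_class, "), ",
      nrow(x$samples), " samples, contact ", round(x$contact_time),
      " s, landing ", round(x$landing_time), " s\n", sep = "")
  invisible(x)
}

interp_position <- function(traj, times) {
  s <- traj$samples
  data.frame(time = times,
             x = stats::approx(s$time, s$x, times)$y,
             y = stats::approx(s$time, s$y, times)$y,
             alt = stats::approx(s$time, s$alt, times)$y)
}

#' Route distance between initial contact and landing
#'
#' Length in NM of the lateral (x, y) polyline between the contact and
#' landing time points; positions at the two endpoints are linearly
#' interpolated between samples.  Invariant under time reparameterization
#' and refinement of the sampling.
#'
#' @param traj a \code{trajectory} whose samples cover
#'   [contact_time, landing_time]
#' @return distance in NM
#' @export
route_distance <- function(traj) {
  s <- traj$samples
  t0 <- traj$contact_time
  t1 <- traj$landing_time
  if (t0 < min(s$time) || t1 > max(s$time)) {
    stop_dfhm("contact/landing window outside sampled times")
  }
  inner <- s$time > t0 & s$time < t1
  p0 <- interp_position(traj, t0)
  p1 <- interp_position(traj, t1)
  px <- c(p0$x, s$x[inner], p1$x)
  py <- c(p0$y, s$y[inner], p1$y)
  sum(sqrt(diff(px)^2 + diff(py)^2))
}

#' Wake-vortex separation rules
#'
#' Lateral minima in NM looked up by (leader wake class, follower wake
#' class), plus a vertical minimum in ft.  The quoted pairs are
#' medium-medium 3 NM and medium-behind-heavy 5 NM; the remaining pairs
#' default to ICAO radar wake-turbulence values (heavy-heavy 4 NM,
#' heavy-behind-medium 3 NM).
#'
#' @param lateral_nm named numeric vector; names \code{"leader-follower"}
#' @param vertical_ft vertical minimum in ft; default 1000
#' @return object of class \code{separation_rules}
#' @export
separation_rules <- function(lateral_nm = c("medium-medium" = 3,
                                            "heavy-medium" = 5,
                                            "heavy-heavy" = 4,
                                            "medium-heavy" = 3),
                             vertical_ft = 1000) {
  if (any(lateral_nm <= 0) || vertical_ft <= 0) {
    stop_dfhm("separation minima must be positive")
  }
  structure(list(lateral_nm = lateral_nm, vertical_ft = vertical_ft),
            class = "separation_rules")
}

#' Read separation rules from JSON
#' @param path JSON file with fields \code{lateral_nm} (object keyed by
#'   "leader-follower") and \code{vertical_ft}
#' @return a \code{separation_rules}
#' @export
read_separation_rules <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  separation_rules(unlist(obj$lateral_nm), obj$vertical_ft)
}

#' Detect losses of separation between two aircraft
#'
#' Lateral and vertical distances are evaluated on the union of both
#' trajectories' time stamps within their overlap (positions linearly
#' interpolated).  A loss of separation is a maximal contiguous interval
#' where the lateral distance is below the wake-vortex minimum for the pair
#' \emph{and} the vertical distance is below the vertical minimum
#' simultaneously.  The first trajectory is treated as the leader for the
#' rules lookup.
#'
#' @param a leader \code{trajectory}
#' @param b follower \code{trajectory}
#' @param rules a \code{separation_rules}
#' @return list with \code{count} and \code{intervals} (data frame with
#'   start/end times in seconds)
#' @export
detect_separation_losses <- function(a, b, rules = separation_rules()) {
  t0 <- max(min(a$samples$time), min(b$samples$time))
  t1 <- min(max(a$samples$time), max(b$samples$time))
  if (t0 >= t1) stop_dfhm("trajectories have no temporal overlap")
  grid <- sort(unique(c(a$samples$time, b$samples$time)))
  grid <- grid[grid >= t0 & grid <= t1]
  pa <- interp_position(a, grid)
  pb <- interp_position(b, grid)
  lat <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  vert <- abs(pa$alt - pb$alt)
  key <- paste0(a$wake_class, "-", b$wake_class)
  req <- rules$lateral_nm[[key]]
  if (is.null(req) || is.na(req)) stop_dfhm("no lateral minimum for pair ", key)
  breach <- lat < req & vert < rules$vertical_ft
  r <- rle(breach)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values)
  intervals <- data.frame(start = grid[starts[hit]], end = grid[ends[hit]])
  list(count = length(hit), intervals = intervals)
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Signed-rank statistic on the differences x - y (zero differences
#' dropped), normal approximation with average ranks for ties, tie-corrected
#' variance and a 0.5 continuity correction.  The reported Z is negative
#' when x tends to be smaller than y.  The two-sided p-value is multiplied
#' by \code{n_comparisons} and capped at 1; the effect size is r = Z /
#' sqrt(N) with N the number of pairs supplied.
#'
#' @param x,y paired numeric vectors (equal length; >= 5 non-zero
#'   differences required)
#' @param n_comparisons Bonferroni multiplier; default 1
#' @return list with \code{statistic} (W+, sum of positive ranks), \code{Z},
#'   \code{p}, \code{p_adjusted}, \code{r}, \code{n} (pairs), \code{n_used}
#'   (non-zero differences)
#' @export
paired_wilcoxon <- function(x, y, n_comparisons = 1) {
  if (length(x) != length(y)) stop_dfhm("x and y must be paired (equal length)")
  n_pairs <- length(x)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_dfhm("all differences are zero")
  if (n < 5) stop_dfhm("need >= 5 non-zero differences, got ", n)
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w_pos - mu) * 0.5
  z <- (w_pos - mu - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p <- min(p, 1)
  list(statistic = w_pos, Z = z, p = p,
       p_adjusted = min(1, p * n_comparisons),
       r = z / sqrt(n_pairs), n = n_pairs, n_used = n)
}

#' Read trajectories from CSV
#'
#' Columns \code{aircraft,wake_class,time_s,x_nm,y_nm,alt_ft}; contact and
#' landing times come from a sidecar CSV with columns
#' \code{aircraft,contact_time_s,landing_time_s}.
#'
#' @param path trajectory CSV
#' @param times_path sidecar CSV with contact/landing times
#' @return list of \code{trajectory} objects
#' @export
read_trajectories_csv <- function(path, times_path) {
  df <- utils::read.csv(path)
  tm <- utils::read.csv(times_path)
  lapply(unique(df$aircraft), function(id) {
    sub <- df[df$aircraft == id, ]
    ti <- tm[tm$aircraft == id, ]
    trajectory(id, sub$wake_class[1],
               data.frame(time = sub$time_s, x = sub$x_nm, y = sub$y_nm,
                          alt = sub$alt_ft),
               ti$contact_time_s[1], ti$landing_time_s[1])
  })
}

#' Write trajectories to CSV (plus sidecar contact/landing times)
#' @param trajs list of \code{trajectory} objects
#' @param path trajectory CSV path
#' @param times_path sidecar CSV path
#' @return \code{path}, invisibly
#' @export
write_trajectories_csv <- function(trajs, path, times_path) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(aircraft = tr$id, wake_class = tr$wake_class,
               time_s = tr$samples$time, x_nm = tr$samples$x,
               y_nm = tr$samples$y, alt_ft = tr$samples$alt)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  tms <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(aircraft = tr$id, contact_time_s = tr$contact_time,
               landing_time_s = tr$landing_time)
  }))
  utils::write.csv(tms, times_path, row.names = FALSE)
  invisible(path)
}
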