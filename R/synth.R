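# Synthetic-data generator.
#
# Produces 25-channel 500 Hz EEG, ISA rating logs and arrival trajectories
# with the statistical structure the analysis pipeline assumes: frontal
# theta power rising and parietal alpha power falling with traffic load,
# ISA ratings linear in load with subject-specific sensitivity, and arrival
# streams where a priority-flight request earns the requesting aircraft a
# shortcut.  Everything is deterministic given the seeds carried by the
# scenario designs and subject profiles.

#' Scenario design
#'
#' @param traffic_load aircraft per hour, one of 25, 35, 45, 55
#' @param priority_event does a priority-flight request occur?
#' @param duration scenario duration in seconds (the study scenarios last
#'   20-25 min; shorter durations are useful for desk-scale simulation)
#' @param request_time scripted time of the priority-flight request
#'   (seconds); the study places it around the 11th minute, default 660
#' @param id integer scenario id
#' @return object of class \code{scenario_design}
#' @export
scenario_design <- function(traffic_load, priority_event = FALSE,
                            duration = 1440, request_time = 660, id = 1L) {
  if (!traffic_load %in% c(25, 35, 45, 55)) {
    stop_dfhm("traffic_load must be one of 25, 35, 45, 55 ac/h")
  }
  structure(list(traffic_load = traffic_load,
                 priority_event = isTRUE(priority_event),
                 duration = duration, request_time = request_time,
                 id = as.integer(id)),
            class = "scenario_design")
}

#' The eight study scenarios: 4 traffic loads x priority event yes/no
#'
#' @param duration scenario duration in seconds, default 24 min
#' @param request_time request time for event scenarios, default 660 s
#' @return list of eight \code{scenario_design} objects (ids 1-8; odd ids
#'   without, even ids with priority event, as load increases)
#' @export
default_designs <- function(duration = 1440, request_time = 660) {
  loads <- c(25, 25, 35, 35, 45, 45, 55, 55)
  prio <- rep(c(FALSE, TRUE), 4)
  lapply(1:8, function(i) {
    scenario_design(loads[i], prio[i], duration, request_time, id = i)
  })
}

#' Subject profile for the synthetic generator
#'
#' Captures the stable, subject-level quantities: how strongly frontal theta
#' rises (\code{theta_gain}) and parietal alpha falls (\code{alpha_loss})
#' per traffic-load level, the subject's true normalized ISA sensitivity
#' \code{isa_s}, band amplitudes and background noise level, and the
#' subject's base seed.
#'
#' @param id subject identifier
#' @param seed base integer seed; all per-scenario seeds derive from it
#' @param theta_gain relative frontal theta amplitude increase per load
#'   level (>= 0)
#' @param task_gain load-independent relative frontal theta increase while
#'   on task (individual task engagement/reactivity trait; >= 0)
#' @param alpha_loss relative parietal alpha amplitude decrease per load
#'   level (>= 0)
#' @param isa_s true normalized ISA workload sensitivity
#' @param amp_theta,amp_alpha oscillation amplitudes in microvolts
#' @param noise_sd background noise standard deviation in microvolts
#' @param mod_sd log-amplitude modulation sd (slow waxing/waning of band
#'   amplitude)
#' @param event_boost relative theta boost in the 2.5 min after a priority
#'   request
#' @return object of class \code{subject_profile}
#' @export
subject_profile <- function(id, seed = 1, theta_gain = 0.06,
                            task_gain = 0.15, alpha_loss = 0.04, isa_s = 0.8,
                            amp_theta = 5.8, amp_alpha = 7.2,
                            noise_sd = 6, mod_sd = 0.12,
                            event_boost = 0.25) {
  stopifnot(theta_gain >= 0, task_gain >= 0, alpha_loss >= 0, noise_sd > 0)
  structure(list(id = id, seed = as.integer(seed), theta_gain = theta_gain,
                 task_gain = task_gain,
                 alpha_loss = alpha_loss, isa_s = isa_s,
                 amp_theta = amp_theta, amp_alpha = amp_alpha,
                 noise_sd = noise_sd, mod_sd = mod_sd,
                 event_boost = event_boost),
            class = "subject_profile")
}

#' Generate a cohort of subject profiles
#'
#' Subject responsiveness (theta gain, alpha loss) varies across the cohort
#' so that paired same-load scenarios share a subject effect; ISA
#' sensitivities are planted in two groups spanning the plausible 0.32-1.23
#' range, \code{n_sensitive} of them high (>= 0.9) and the rest low
#' (<= 0.68), giving a known ground-truth median split.
#'
#' @param n cohort size, default 21
#' @param seed cohort seed
#' @param n_sensitive number of high-sensitivity subjects, default 12
#' @return list of \code{subject_profile} objects
#' @export
cohort_profiles <- function(n = 21, seed = 1, n_sensitive = 12) {
  stopifnot(n_sensitive <= n)
  with_seed(seed, {
    gains <- pmax(0.015, stats::rnorm(n, 0.05, 0.025))
    task_gains <- pmax(0.02, stats::rnorm(n, 0.15, 0.15))
    losses <- pmax(0.01, stats::rnorm(n, 0.04, 0.02))
    s_true <- c(stats::runif(n_sensitive, 0.9, 1.23),
                stats::runif(n - n_sensitive, 0.32, 0.68))
    lapply(seq_len(n), function(i) {
      subject_profile(id = sprintf("S%02d", i), seed = seed + 1000L * i,
                      theta_gain = gains[i], task_gain = task_gains[i],
                      alpha_loss = losses[i], isa_s = s_true[i])
    })
  })
}

load_level <- function(traffic_load) match(traffic_load, c(25, 35, 45, 55))

# slow log-normal amplitude modulation, correlation time ~1.5 s
slow_modulation <- function(t, sd) {
  grid <- seq(0, max(t) + 5, by = 1)
  z <- as.numeric(stats::filter(stats::rnorm(length(grid)), 0.4, "recursive"))
  z <- z / stats::sd(z) * sd
  exp(stats::approx(grid, z, t, rule = 2)$y - sd^2 / 2)
}

#' Generate a synthetic EEG recording for one subject and scenario
#'
#' 25 channels at 500 Hz: an AR(1) 1/f-like background plus per-channel
#' theta (~6 Hz) and alpha (~10 Hz) oscillators with slowly modulated
#' amplitudes.  Theta is frontally weighted and its amplitude increases
#' with the traffic-load level; alpha is parietally weighted and decreases
#' with load.  The load effect is gated by an envelope that is zero during
#' the first minute (the quiet settle-in that serves as the z-score
#' baseline) and ramps to one by 90 s as traffic builds up.  A priority
#' event adds a transient extra theta boost for 150 s after the request;
#' optional blink artifacts are frontally weighted half-sine transients
#' with Poisson arrivals.  The event trigger is recorded in the event list
#' as \code{"PRIORITY_REQUEST"}.
#'
#' @param profile a \code{subject_profile}
#' @param design a \code{scenario_design}
#' @param montage montage defining channels and regions
#' @param fs sampling rate, Hz (the study rate is 500)
#' @param include_blinks add blink artifacts?
#' @param blink_rate blinks per minute when enabled
#' @param seed scenario seed; defaults to a deterministic combination of
#'   the profile seed and the design id
#' @return an \code{eeg_recording}
#' @export
generate_eeg <- function(profile, design, montage = default_montage(),
                         fs = 500, include_blinks = FALSE, blink_rate = 8,
                         seed = profile$seed + 17L * design$id) {
  n <- round(design$duration * fs)
  t <- (seq_len(n) - 1) / fs
  ch <- montage$electrode_names
  nch <- length(ch)
  lvl <- load_level(design$traffic_load)
  region <- montage$region[ch]
  w_theta <- c(frontal = 1, other = 0.3, parietal = 0.1)[region]
  w_alpha <- c(frontal = 0.1, other = 0.3, parietal = 1)[region]
  w_blink <- stats::setNames(0.05 + 0.95 * pmax(montage$positions[ch, "y"], 0)^2, ch)

  env <- pmin(1, pmax(0, (t - 60) / 30))    # load effect absent in baseline
  theta_level <- 1 + (profile$task_gain + profile$theta_gain * lvl) * env
  # task engagement also depresses alpha (same trait), on top of the load
  alpha_level <- pmax(0.15, 1 - (0.5 * profile$task_gain +
                                   profile$alpha_loss * lvl) * env)
  events <- NULL
  with_seed(seed, {
    if (design$priority_event) {
      w <- t >= design$request_time & t < design$request_time + 150
      bump <- numeric(n)
      bump[w] <- sin(pi * (t[w] - design$request_time) / 150)
      theta_level <- theta_level * (1 + profile$event_boost * bump)
      events <- data.frame(label = "PRIORITY_REQUEST",
                           time = design$request_time)
    }
    f_th <- 6 + stats::runif(1, -0.5, 0.5)
    f_al <- 10 + stats::runif(1, -0.5, 0.5)
    mod_th <- slow_modulation(t, profile$mod_sd)
    mod_al <- slow_modulation(t, profile$mod_sd)
    a_th <- profile$amp_theta * theta_level * mod_th
    a_al <- profile$amp_alpha * alpha_level * mod_al
    data <- matrix(0, nch, n, dimnames = list(ch, NULL))
    phases_th <- stats::runif(nch, 0, 2 * pi)
    phases_al <- stats::runif(nch, 0, 2 * pi)
    for (c_i in seq_len(nch)) {
      noise <- as.numeric(stats::filter(stats::rnorm(n), 0.95, "recursive"))
      noise <- noise / stats::sd(noise) * profile$noise_sd
      data[c_i, ] <- noise +
        w_theta[c_i] * a_th * sin(2 * pi * f_th * t + phases_th[c_i]) +
        w_alpha[c_i] * a_al * sin(2 * pi * f_al * t + phases_al[c_i])
    }
    if (include_blinks) {
      n_blinks <- stats::rpois(1, blink_rate * design$duration / 60)
      if (n_blinks > 0) {
        onsets <- stats::runif(n_blinks, 0, design$duration - 0.5)
        durs <- stats::runif(n_blinks, 0.3, 0.5)
        amps <- stats::runif(n_blinks, 60, 120)
        for (bi in seq_len(n_blinks)) {
          i0 <- floor(onsets[bi] * fs) + 1
          len <- round(durs[bi] * fs)
          shape <- amps[bi] * sin(pi * seq_len(len) / len)
          span <- i0:min(i0 + len - 1, n)
          data[, span] <- data[, span] +
            outer(w_blink, shape[seq_along(span)])
        }
      }
    }
    eeg_recording(data, fs, ch, reference = "Cz", events = events)
  })
}

#' Generate separable three-class DFHM training data
#'
#' Gaussian blobs in the z-scored feature space: low workload centred at
#' zero, moderate and high shifted by +separation and +2*separation on the
#' frontal-theta features and by -separation/2 and -separation on the
#' parietal-alpha features, with unit-like within-class spread.  With the
#' default separation of 2 the cohort means sit about two within-class
#' standard deviations apart.
#'
#' @param n_per_class samples per class
#' @param separation between-class shift in z-units
#' @param sd within-class standard deviation
#' @param montage montage fixing the feature names/order
#' @param seed integer seed
#' @return list with \code{features} (a \code{dfhm_features}) and
#'   \code{labels} (integer classes 1/2/3)
#' @export
generate_training_dfhm <- function(n_per_class = 100, separation = 2,
                                   sd = 1, montage = default_montage(),
                                   seed = 1) {
  fr <- frontal_electrodes(montage)
  pa <- parietal_electrodes(montage)
  nm <- c(paste0(fr, ".theta"), paste0(pa, ".alpha"))
  n_f <- length(fr); n_p <- length(pa)
  with_seed(seed, {
    labels <- rep(1:3, each = n_per_class)
    mu_theta <- (labels - 1) * separation
    mu_alpha <- -(labels - 1) * separation / 2
    X <- cbind(matrix(stats::rnorm(length(labels) * n_f, mu_theta, sd),
                      ncol = n_f),
               matrix(stats::rnorm(length(labels) * n_p, mu_alpha, sd),
                      ncol = n_p))
    colnames(X) <- nm
    perm <- sample(length(labels))
    feats <- structure(list(features = X[perm, , drop = FALSE],
                            feature_names = nm,
                            times = 0.5 * (seq_along(labels) - 1)),
                       class = "dfhm_features")
    list(features = feats, labels = labels[perm])
  })
}

#' Generate ISA ratings for one subject over a set of scenarios
#'
#' Ratings arrive every 300 s.  The expected rating is linear in traffic
#' load with the subject's true normalized sensitivity \code{profile$isa_s}
#' mapped to a raw slope around a mid-scale rating of 3 at the load-scale
#' mean of 40 ac/h; Gaussian noise is added, then ratings are rounded to
#' integers and clipped to the 1-5 scale (set \code{round = FALSE} for
#' continuous ratings).
#'
#' @param profile a \code{subject_profile}
#' @param designs list of \code{scenario_design} objects
#' @param noise_sd rating noise standard deviation, default 0.5
#' @param round round to integer ratings? default TRUE
#' @param seed integer seed; default derived from the profile seed
#' @return data frame with columns subject, scenario, time_s, rating,
#'   traffic_load
#' @export
generate_isa <- function(profile, designs, noise_sd = 0.5, round = TRUE,
                         seed = profile$seed + 7L) {
  slope <- profile$isa_s * 3 / 40       # s* * Ibar / Lbar with Ibar = 3
  intercept <- 3 - slope * 40
  with_seed(seed, {
    rows <- lapply(designs, function(d) {
      k <- floor(d$duration / 300)
      if (k == 0) return(NULL)
      expected <- intercept + slope * d$traffic_load
      r <- expected + stats::rnorm(k, 0, noise_sd)
      if (round) r <- base::round(r)
      r <- pmin(5, pmax(1, r))
      data.frame(subject = profile$id, scenario = d$id,
                 time_s = 300 * seq_len(k), rating = r,
                 traffic_load = d$traffic_load)
    })
    do.call(rbind, rows)
  })
}

# Nominal arrival route: a gentle C-shaped arc (18-degree turns every 4 NM)
# from the entry fix onto a final-approach fix at (6, 2) and the runway at
# the origin, about 46 NM in total.  The gentle curvature keeps the lateral
# distance between in-trail aircraft essentially equal to their along-track
# spacing, so the nominal stream never breaches wake-vortex minima even at
# the tightest 55 ac/h spacing; `stretch` lengthens the entry leg.
arrival_waypoints <- function(stretch = 0) {
  wp <- rbind(
    c(-5.78, 24.69), c(-1.99, 25.96), c(2.01, 25.99), c(5.83, 24.78),
    c(9.08, 22.46), c(11.46, 19.24), c(12.72, 15.44), c(12.75, 11.44),
    c(11.54, 7.63), c(9.22, 4.38), c(6.00, 2.00), c(0.00, 0.00))
  if (stretch > 0) {
    u <- (wp[1, ] - wp[2, ]) / sqrt(sum((wp[1, ] - wp[2, ])^2))
    wp[1, ] <- wp[1, ] + stretch * u
  }
  wp
}

# final-approach fix the priority shortcut aims at
FINAL_FIX <- c(6, 2)

polyline_length <- function(wp) sum(sqrt(rowSums(diff(wp)^2)))

# Sample a polyline at constant ground speed; returns time/x/y from t0.
sample_route <- function(wp, t0, speed, dt) {
  seg_len <- sqrt(rowSums(diff(wp)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  tt <- seq(0, total / speed, by = dt)
  if (tt[length(tt)] < total / speed) tt <- c(tt, total / speed)
  s <- tt * speed
  x <- stats::approx(cum, wp[, 1], s)$y
  y <- stats::approx(cum, wp[, 2], s)$y
  data.frame(time = t0 + tt, x = x, y = y)
}

#' Generate arrival trajectories for a scenario
#'
#' Aircraft enter at the design's rate and fly a common trombone arrival
#' route (~44-48 NM contact to landing) at 180 kt, descending from 8000 ft
#' to the runway.  When the scenario has a priority event, the requesting
#' aircraft (the one still on its downwind leg at the request time) is
#' rerouted directly to the final-approach fix, which strictly shortens its
#' route.  Optionally, \code{n_violations} extra aircraft pairs are planted
#' away from the arrival stream, each engineered to produce exactly one
#' loss of separation (lateral dip to 2.8 NM at under 1000 ft vertical),
#' giving a known ground-truth violation count.
#'
#' @param design a \code{scenario_design}
#' @param seed integer seed
#' @param n_violations number of planted separation losses
#' @param dt sampling interval in seconds, default 5
#' @return list with \code{trajectories} (list of \code{trajectory}),
#'   \code{requester} (id of the prioritized aircraft or NA),
#'   \code{n_violations}
#' @export
generate_trajectories <- function(design, seed = 1, n_violations = 0, dt = 5) {
  speed <- 180 / 3600            # NM per second
  rate <- design$traffic_load
  n_ac <- max(1L, round(rate * design$duration / 3600))  # always >= 1 arrival
  with_seed(seed, {
    # one stretch per scenario: identical routes keep the in-trail gap
    # exactly at the entry spacing, so the nominal stream stays separated
    stretch0 <- stats::runif(1, 0, 2)
    trajs <- list()
    contacts <- (seq_len(n_ac) - 1) * 3600 / rate
    for (k in seq_len(n_ac)) {
      wp <- arrival_waypoints(stretch0)
      path <- sample_route(wp, contacts[k], speed, dt)
      land <- path$time[nrow(path)]
      alt <- 8000 * (land - path$time) / (land - contacts[k])
      trajs[[k]] <- trajectory(sprintf("AC%02d", k), "medium",
                               cbind(path, alt = alt), contacts[k], land)
    }
    requester <- NA_character_
    if (design$priority_event) {
      rt <- design$request_time
      age <- rt - contacts
      cand <- which(age >= 0 & age <= 280)   # still on the early arc
      ri <- if (length(cand) > 0) max(cand) else max(which(age >= 0))
      tr <- trajs[[ri]]
      keep <- tr$samples$time <= rt
      pos <- interp_position(tr, rt)
      wp2 <- rbind(c(pos$x, pos$y), FINAL_FIX, c(0, 0))
      path2 <- sample_route(wp2, rt, speed, dt)
      land2 <- path2$time[nrow(path2)]
      head_ <- tr$samples[keep, c("time", "x", "y")]
      new_path <- rbind(head_, path2[-1, ])
      alt2 <- 8000 * pmax(land2 - new_path$time, 0) / (land2 - tr$contact_time)
      trajs[[ri]] <- trajectory(tr$id, tr$wake_class,
                                cbind(new_path, alt = alt2),
                                tr$contact_time, land2)
      requester <- tr$id
    }
    if (n_violations > 0) {
      for (v in seq_len(n_violations)) {
        y0 <- 50 + 12 * v
        t0 <- 100 * v
        tt <- seq(t0, t0 + 600, by = dt)
        lead <- data.frame(time = tt, x = 40 + speed * (tt - t0), y = y0,
                           alt = 5000)
        offset <- 6 - 3.2 * pmax(0, 1 - abs(tt - (t0 + 230)) / 60)  # dips to 2.8
        foll <- data.frame(time = tt, x = 40 + speed * (tt - t0),
                           y = y0 + offset, alt = 4600)
        trajs[[length(trajs) + 1]] <-
          trajectory(sprintf("VL%02d", v), "medium", lead, t0, t0 + 600)
        trajs[[length(trajs) + 1]] <-
          trajectory(sprintf("VF%02d", v), "medium", foll, t0, t0 + 600)
      }
    }
    list(trajectories = trajs, requester = requester,
         n_violations = n_violations)
  })
}

#' Count losses of separation over all aircraft pairs
#'
#' Applies \code{\link{detect_separation_losses}} to every unordered pair
#' with overlapping time support, treating the earlier-contact aircraft as
#' the leader, and sums the counts.
#'
#' @param trajs list of \code{trajectory} objects
#' @param rules a \code{separation_rules}
#' @return total number of losses of separation
#' @export
count_separation_losses <- function(trajs, rules = separation_rules()) {
  total <- 0
  n <- length(trajs)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- trajs[[i]]; b <- trajs[[j]]
      t0 <- max(min(a$samples$time), min(b$samples$time))
      t1 <- min(max(a$samples$time), max(b$samples$time))
      if (t0 >= t1) next
      if (a$contact_time > b$contact_time) { tmp <- a; a <- b; b <- tmp }
      total <- total + detect_separation_losses(a, b, rules)$count
    }
  }
  total
}
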