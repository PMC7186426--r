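test_that("scenario designs form the 2 x 4 crossing", {
  designs <- default_designs()
  expect_length(designs, 8)
  grid <- data.frame(load = vapply(designs, `[[`, 0, "traffic_load"),
                     prio = vapply(designs, `[[`, TRUE, "priority_event"))
  expect_equal(nrow(unique(grid)), 8)
  expect_setequal(grid$load, c(25, 35, 45, 55))
  expect_error(scenario_design(40), "traffic_load")
})

test_that("generated EEG has the study shape and is seed-deterministic", {
  p <- subject_profile("S1", seed = 4)
  d <- scenario_design(35, FALSE, duration = 5, id = 1)
  rec <- generate_eeg(p, d, MONT)
  expect_equal(rec$fs, 500)
  expect_equal(nrow(rec$data), 25)
  expect_equal(ncol(rec$data), 5 * 500)
  rec2 <- generate_eeg(p, d, MONT)
  expect_identical(rec$data, rec2$data)
  expect_false(identical(generate_eeg(p, d, MONT, seed = 99)$data, rec$data))
})

test_that("frontal theta rises and parietal alpha falls with load", {
  # cohort-mean tendencies at the raw band-power level, 20 subjects
  profs <- cohort_profiles(20, seed = 61, n_sensitive = 10)
  th <- al <- matrix(NA, 20, 2)
  for (i in seq_len(20)) {
    for (j in 1:2) {
      load <- c(25, 55)[j]
      rec <- generate_eeg(profs[[i]],
                          scenario_design(load, FALSE, duration = 120,
                                          id = j), MONT)
      segs <- segment_recording(rec)
      task <- segs$start_times >= 90
      bp <- band_power_multi(segs, list(c(4, 8), c(8, 12)))
      th[i, j] <- mean(bp[[1]]$values[task, "Fz"])
      al[i, j] <- mean(bp[[2]]$values[task, "Pz"])
    }
  }
  expect_gt(mean(th[, 2]), mean(th[, 1]))   # Fz theta: 55 ac/h > 25 ac/h
  expect_lt(mean(al[, 2]), mean(al[, 1]))   # Pz alpha: 55 ac/h < 25 ac/h
  # baseline-period Fz theta sits in a plausible absolute range (uV^2)
  rec <- generate_eeg(profs[[1]],
                      scenario_design(25, FALSE, duration = 60, id = 1), MONT)
  base <- mean(band_power(segment_recording(rec), c(4, 8))$values[, "Fz"])
  expect_gt(base, 10)
  expect_lt(base, 40)
})

test_that("ISA ratings follow the design grid and the planted slope", {
  p0 <- subject_profile("S0", seed = 5, isa_s = 0)
  d20 <- scenario_design(45, FALSE, duration = 1200, id = 1)
  isa <- generate_isa(p0, list(d20), noise_sd = 0)
  expect_equal(nrow(isa), 4)                  # 20 min -> 4 ratings
  expect_equal(isa$time_s, c(300, 600, 900, 1200))
  expect_true(all(isa$rating == isa$rating[1]))  # s* = 0, no noise
  p1 <- subject_profile("S1", seed = 5, isa_s = 1)
  isa1 <- generate_isa(p1, default_designs(duration = 1500), noise_sd = 0,
                       round = FALSE)
  fitted <- fit_isa_line(isa1)
  expect_equal(sensitivity_index(fitted$slope, fitted$intercept)$s_a, 1,
               tolerance = 1e-10)
})

test_that("trajectory streams honor rate, priority shortcut and plants", {
  d <- scenario_design(25, FALSE, duration = 1440)
  g <- generate_trajectories(d, seed = 4)
  expect_length(g$trajectories, 10)           # 25 ac/h x 24 min
  expect_equal(count_separation_losses(g$trajectories), 0)
  dp <- scenario_design(25, TRUE, duration = 1440)
  gp <- generate_trajectories(dp, seed = 4)
  ids <- vapply(gp$trajectories, `[[`, "", "id")
  ri <- match(gp$requester, ids)
  expect_lt(route_distance(gp$trajectories[[ri]]),
            route_distance(g$trajectories[[ri]]))
  # planted violations are recovered exactly, also at the tightest spacing
  g2 <- generate_trajectories(scenario_design(55, FALSE, duration = 1440),
                              seed = 7, n_violations = 2)
  expect_equal(count_separation_losses(g2$trajectories), 2)
})
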