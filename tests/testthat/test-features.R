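test_that("segmentation yields 2T-1 full one-second segments", {
  rec60 <- eeg_recording(matrix(0, 1, 30000) + rnorm(30000), 500, "Fz")
  expect_length(segment_recording(rec60)$start_times, 119)
  rec1 <- eeg_recording(matrix(rnorm(500), 1), 500, "Fz")
  expect_length(segment_recording(rec1)$start_times, 1)
  # 1.4 s: the 0.5-start segment lacks full support and is dropped
  rec14 <- eeg_recording(matrix(rnorm(700), 1), 500, "Fz")
  expect_length(segment_recording(rec14)$start_times, 1)
  expect_error(segment_recording(eeg_recording(matrix(rnorm(400), 1), 500,
                                               "Fz")), "shorter")
})

test_that("band power matches the analytic sinusoid value and band bounds", {
  rec <- sine_recording(6, amps = 3, duration = 10)
  segs <- segment_recording(rec)
  th <- band_power(segs, c(4, 8))
  al <- band_power(segs, c(8, 12))
  expect_equal(mean(th$values), 3^2 / 2, tolerance = 0.01)  # a^2/2
  expect_lt(mean(al$values), 0.01 * mean(th$values))
  # 8 Hz falls in alpha, not theta (half-open bands)
  rec8 <- sine_recording(8, amps = 2, duration = 4)
  segs8 <- segment_recording(rec8)
  expect_equal(mean(band_power(segs8, c(8, 12))$values), 2, tolerance = 0.01)
  expect_lt(mean(band_power(segs8, c(4, 8))$values), 0.02)
})

test_that("Parseval holds and theta+alpha never exceed total power", {
  withr::with_seed(21, {
    x <- rnorm(1500)
  })
  rec <- eeg_recording(matrix(x, 1), 500, "Fz")
  segs <- segment_recording(rec)
  total <- band_power(segs, c(0, 250))$values
  msq <- vapply(segs$start_times,
                function(s) mean(x[(s * 500 + 1):(s * 500 + 500)]^2),
                numeric(1))
  expect_equal(as.numeric(total), msq, tolerance = 1e-6)
  sub <- band_power(segs, c(4, 8))$values + band_power(segs, c(8, 12))$values
  expect_true(all(sub <= total))
})

test_that("baseline statistics use the 119 first-minute segments", {
  withr::with_seed(3, {
    rec <- eeg_recording(matrix(rnorm(25 * 45000, sd = 10), 25), 500,
                         MONT$electrode_names)
  })
  bp <- band_power(segment_recording(rec), c(4, 8))
  st <- baseline_stats(bp, 60)
  expect_equal(st$n_segments, 119)
  expect_true(all(st$sd > 0))
})

test_that("baseline estimates recover known per-electrode moments", {
  # sampling oracle: band powers drawn directly from a known distribution
  withr::with_seed(14, {
    mu <- c(Fz = 20, Pz = 30)
    sd0 <- c(Fz = 4, Pz = 6)
    v <- cbind(Fz = rnorm(119, mu["Fz"], sd0["Fz"]),
               Pz = rnorm(119, mu["Pz"], sd0["Pz"]))
  })
  bp <- structure(list(values = v, band = c(4, 8),
                       start_times = 0.5 * (0:118)),
                  class = "band_power_matrix")
  st <- baseline_stats(bp, 60)
  se_mean <- sd0 / sqrt(119)
  expect_true(all(abs(st$mean - mu) < 3 * se_mean))
  se_sd <- sd0 / sqrt(2 * 118)
  expect_true(all(abs(st$sd - sd0) < 3 * se_sd))
})

test_that("degenerate baselines are refused", {
  bp <- structure(list(values = matrix(5, 10, 2,
                                       dimnames = list(NULL, c("Fz", "Pz"))),
                       band = c(4, 8), start_times = 0.5 * (0:9)),
                  class = "band_power_matrix")
  expect_error(baseline_stats(bp, 5), "degenerate")
})

test_that("z-scoring self-normalizes the baseline and is affine-invariant", {
  withr::with_seed(6, {
    v <- matrix(rexp(119 * 3, 1 / 20), 119, 3,
                dimnames = list(NULL, c("Fz", "FCz", "Pz")))
  })
  bp <- structure(list(values = v, band = c(4, 8),
                       start_times = 0.5 * (0:118)),
                  class = "band_power_matrix")
  st <- baseline_stats(bp, 60)
  z <- zscore_band_power(bp, st)
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # scaling all powers and baselines by c > 0 leaves z-scores unchanged
  bp2 <- bp; bp2$values <- bp$values * 3.7
  z2 <- zscore_band_power(bp2, baseline_stats(bp2, 60))
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # pointwise contract
  one <- bp; one$values <- matrix(st$mean + 2 * st$sd, 1, 3, byrow = TRUE,
                                  dimnames = list(NULL, colnames(v)))
  one$start_times <- 0
  expect_equal(unname(zscore_band_power(one, st)$values[1, ]), rep(2, 3))
  # missing electrode statistics are an error
  st2 <- st; st2$mean <- st$mean[1:2]; st2$sd <- st$sd[1:2]
  names(st2$mean) <- names(st2$sd) <- c("Fz", "FCz")
  expect_error(zscore_band_power(bp, st2), "Pz")
})

test_that("DFHM assembly follows montage order and flags grid mismatches", {
  k <- 5
  zt <- structure(list(values = matrix(0, k, 25,
                                       dimnames = list(NULL, MONT$electrode_names)),
                       band = c(4, 8), start_times = 0.5 * (0:(k - 1))),
                  class = "band_power_matrix")
  za <- zt; za$band <- c(8, 12)
  maps <- build_dfhm(zt, za, MONT)
  expect_length(maps$feature_names, 20)
  expect_identical(maps$feature_names,
                   c(paste0(frontal_electrodes(MONT), ".theta"),
                     paste0(parietal_electrodes(MONT), ".alpha")))
  expect_true(all(maps$features == 0))
  za$start_times <- za$start_times + 0.5
  expect_error(build_dfhm(zt, za, MONT), "grids")
})

test_that("DFHM CSV export round-trips features and names", {
  withr::with_seed(31, {
    zt <- structure(list(values = matrix(rnorm(3 * 25), 3, 25,
                                         dimnames = list(NULL, MONT$electrode_names)),
                         band = c(4, 8), start_times = c(0, 0.5, 1)),
                    class = "band_power_matrix")
  })
  za <- zt; za$band <- c(8, 12)
  maps <- build_dfhm(zt, za, MONT)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dfhm_csv(maps, path)
  back <- read_dfhm_csv(path)
  expect_identical(back$feature_names, maps$feature_names)
  expect_equal(unname(back$features), unname(maps$features))
})
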