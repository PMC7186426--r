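straight <- trajectory("S", "medium",
                       data.frame(time = c(0, 100, 200),
                                  x = c(0, 5, 10), y = 0,
                                  alt = c(6000, 3000, 0)), 0, 200)

test_that("route distance measures the contact-to-landing polyline", {
  expect_equal(route_distance(straight), 10)
  bent <- trajectory("B", "medium",
                     data.frame(time = c(0, 60, 120),
                                x = c(0, 3, 3), y = c(0, 0, 4),
                                alt = c(3000, 2000, 0)), 0, 120)
  expect_equal(route_distance(bent), 7)
  # endpoints interpolate linearly inside the sampled span
  part <- trajectory("P", "medium", bent$samples, 30, 90)
  expect_equal(route_distance(part), 1.5 + 2)
  expect_error(route_distance(trajectory("X", "medium", bent$samples,
                                         0, 120 + 1e-9)), "outside")
})

test_that("route distance is invariant to refinement, time warp, shifts", {
  wp <- data.frame(time = c(0, 50, 130, 200),
                   x = c(0, 4, 4, 9), y = c(0, 0, 3, 3),
                   alt = c(5000, 4000, 2000, 0))
  base <- trajectory("A", "medium", wp, 0, 200)
  d0 <- route_distance(base)
  # densify samples along the same path
  tt <- seq(0, 200, by = 1)
  dense <- trajectory("A", "medium",
                      data.frame(time = tt,
                                 x = approx(wp$time, wp$x, tt)$y,
                                 y = approx(wp$time, wp$y, tt)$y,
                                 alt = approx(wp$time, wp$alt, tt)$y), 0, 200)
  expect_equal(route_distance(dense), d0, tolerance = 1e-9)
  # nonlinear time reparameterization visiting the same vertices
  warp <- wp; warp$time <- c(0, 20, 180, 200)
  expect_equal(route_distance(trajectory("A", "medium", warp, 0, 200)), d0)
  # translation invariance and linear spatial scaling
  shift <- wp; shift$x <- wp$x + 7; shift$y <- wp$y - 2
  expect_equal(route_distance(trajectory("A", "medium", shift, 0, 200)), d0)
  scaled <- wp; scaled$x <- wp$x * 3; scaled$y <- wp$y * 3
  expect_equal(route_distance(trajectory("A", "medium", scaled, 0, 200)),
               3 * d0)
})

test_that("separation losses require both minima breached simultaneously", {
  mk <- function(ygap, altgap, wake = "medium") {
    a <- trajectory("L", "medium",
                    data.frame(time = seq(0, 300, 10), x = seq(0, 15, 0.5),
                               y = 0, alt = 5000), 0, 300)
    # follower converges laterally to ygap in mid-flight then diverges
    tt <- seq(0, 300, 10)
    dip <- pmax(0, 1 - abs(tt - 150) / 60)
    b <- trajectory("F", wake,
                    data.frame(time = tt, x = seq(0, 15, 0.5),
                               y = 8 - (8 - ygap) * dip, alt = 5000 - altgap),
                    0, 300)
    list(a = a, b = b)
  }
  # 2.9 NM lateral at 900 ft vertical: one loss (3 NM medium-medium rule)
  p <- mk(2.9, 900)
  res <- detect_separation_losses(p$a, p$b)
  expect_equal(res$count, 1)
  expect_equal(nrow(res$intervals), 1)
  # same lateral dip but 1200 ft vertical: conjunction fails
  expect_equal(detect_separation_losses(mk(2.9, 1200)$a,
                                        mk(2.9, 1200)$b)$count, 0)
  # medium following heavy: the 5 NM wake rule applies at 4 NM / 500 ft
  q <- mk(4, 500)
  q$a$wake_class <- "heavy"
  expect_equal(detect_separation_losses(q$a, q$b)$count, 1)
  # the same geometry between two mediums is legal (4 > 3 NM)
  expect_equal(detect_separation_losses(mk(4, 500)$a, mk(4, 500)$b)$count, 0)
  # disjoint time supports are an error
  late <- trajectory("Z", "medium",
                     data.frame(time = c(400, 500), x = 0:1, y = 0,
                                alt = c(1000, 0)), 400, 500)
  expect_error(detect_separation_losses(p$a, late), "overlap")
})

test_that("signed-rank Z follows the Table-style sign convention", {
  withr::with_seed(12, {
    x <- rnorm(12)
  })
  y <- x + 1
  w <- paired_wilcoxon(x, y, n_comparisons = 1)
  expect_lt(w$Z, 0)                       # x below y -> negative Z
  expect_lt(w$r, 0)
  expect_equal(w$r, w$Z / sqrt(12))
  # Bonferroni multiplies and caps at 1
  expect_equal(paired_wilcoxon(x, y, n_comparisons = 4)$p_adjusted,
               min(1, w$p * 4))
  z <- c(0.3, -0.1, 0.2, -0.25, 0.15, -0.3, 0.05, -0.05)
  expect_equal(paired_wilcoxon(z + 10, rev(z) + 10, 4)$p_adjusted, 1)
  expect_error(paired_wilcoxon(x, x), "zero")
  expect_error(paired_wilcoxon(x[1:4], y[1:4]), ">= 5")
})

test_that("the normal approximation tracks the exact null distribution", {
  # spot check at n = 8; the full n <= 10 sweep runs in the acceptance suite
  n <- 8
  cdf <- exact_signed_rank_cdf(n)
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  w <- 0:(n * (n + 1) / 2)
  expect_lt(max(abs(pnorm((w + 0.5 - mu) / sig) - cdf)), 0.02)
  # and the package p agrees with stats::wilcox.test's normal path
  withr::with_seed(13, {
    x <- rnorm(9)
    y <- rnorm(9)
  })
  ours <- paired_wilcoxon(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("trajectory CSV and rules JSON round-trip", {
  d <- scenario_design(25, TRUE, duration = 1440)
  g <- generate_trajectories(d, seed = 6)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(g$trajectories, p1, p2)
  back <- read_trajectories_csv(p1, p2)
  expect_length(back, length(g$trajectories))
  expect_equal(route_distance(back[[1]]),
               route_distance(g$trajectories[[1]]))
  rj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lateral_nm = list(`medium-medium` = 3,
                                              `heavy-medium` = 5,
                                              `heavy-heavy` = 4,
                                              `medium-heavy` = 3),
                            vertical_ft = 1000), rj, auto_unbox = TRUE)
  rules <- read_separation_rules(rj)
  expect_equal(unname(rules$lateral_nm["heavy-medium"]), 5)
  expect_error(separation_rules(vertical_ft = -5), "positive")
})
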