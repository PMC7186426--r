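test_that("constant tables produce zero F for every within effect", {
  tab <- make_condition_table(n = 8)
  tab$value <- 42
  a <- rm_anova_2way(tab)
  expect_true(all(a$table$F == 0))
  expect_true(all(a$table$peta2 == 0))
})

test_that("a pure load effect yields load p ~ 0 and zero priority F", {
  # hand oracle: +10 per load step for every subject, no noise
  tab <- make_condition_table(n = 6, load_shift = 10, subj_sd = 3, seed = 2)
  a <- rm_anova_2way(tab)
  tabF <- a$table
  # SS_A = n*b*sum((m_i - m)^2) with level means -15,-5,5,15 around 0
  expect_equal(tabF$SS[tabF$effect == "traffic_load"],
               6 * 2 * sum(c(-15, -5, 5, 15)^2))
  expect_lt(tabF$p[tabF$effect == "traffic_load"], 1e-10)
  expect_equal(tabF$F[tabF$effect == "priority"], 0)
})

test_that("the within-subject decomposition matches car::Anova", {
  skip_if_not_installed("car")
  tab <- make_condition_table(n = 15, load_shift = 4, prio_shift = 2,
                              subj_sd = 4, noise_sd = 5, seed = 7)
  a <- rm_anova_2way(tab)
  Y <- matrix(NA, 15, 8)
  k <- 0
  for (p in c(FALSE, TRUE)) for (l in c(25, 35, 45, 55)) {
    k <- k + 1
    sel <- tab$priority == p & tab$traffic_load == l
    Y[, k] <- tab$value[sel][order(tab$subject[sel])]
  }
  av <- suppressWarnings(
    summary(car::Anova(stats::lm(Y ~ 1),
                       idata = data.frame(load = factor(rep(c(25, 35, 45, 55), 2)),
                                          prio = factor(rep(0:1, each = 4))),
                       idesign = ~ load * prio, type = 3),
            multivariate = FALSE))
  ref <- av$univariate.tests
  expect_equal(a$table$F,
               unname(ref[c("load", "prio", "load:prio"), "F value"]))
  expect_equal(a$table$eps[c(1, 3)],
               unname(av$pval.adjustments[c("load", "load:prio"), "GG eps"]))
  # sums-of-squares decomposition closes
  expect_equal(Reduce(`+`, a$ss[setdiff(names(a$ss), "total")]),
               a$ss$total, tolerance = 1e-10)
})

test_that("epsilon and partial eta squared stay in their ranges", {
  withr::with_seed(30, {
    for (i in 1:5) {
      tab <- make_condition_table(n = 10, load_shift = runif(1, 0, 5),
                                  subj_sd = 3, noise_sd = 4, seed = 100 + i)
      a <- rm_anova_2way(tab)
      expect_true(all(a$table$eps >= 1 / 3 - 1e-12 & a$table$eps <= 1 + 1e-12))
      expect_true(all(a$table$peta2 >= 0 & a$table$peta2 <= 1))
    }
  })
})

test_that("incomplete tables are refused rather than imputed", {
  tab <- make_condition_table(n = 5)
  expect_error(rm_anova_2way(tab[-1, ]), "incomplete")
  expect_error(rm_anova_2way(rbind(tab, tab[1, ])), "incomplete")
})

test_that("Bonferroni post-hocs enumerate pairs and flag the planted one", {
  tab <- make_condition_table(n = 10, noise_sd = 2, seed = 5)
  # plant separation between levels 1 and 4 only
  lvl <- match(tab$traffic_load, c(25, 35, 45, 55))
  tab$value <- tab$value + ifelse(lvl == 4, 8, 0) - ifelse(lvl == 1, 8, 0)
  ph <- bonferroni_posthoc(tab, "traffic_load")
  expect_equal(nrow(ph), 6)
  expect_equal(ph$p_adjusted, pmin(1, ph$p * 6))
  best <- which.min(ph$p_adjusted)
  expect_setequal(c(ph$level1[best], ph$level2[best]), c("25", "55"))
  # identical levels give adjusted p of 1
  flat <- make_condition_table(n = 6)
  flat$value <- 10 + as.numeric(flat$subject)
  expect_true(all(bonferroni_posthoc(flat, "traffic_load")$p_adjusted == 1))
})

test_that("mixed ANOVA matches car and is symmetric in cluster labels", {
  skip_if_not_installed("car")
  cl <- rep(c("sensitive", "not"), c(12, 9))
  tab <- make_condition_table(n = 21, subj_sd = 5, noise_sd = 5, seed = 11,
                              cluster = cl)
  lvl <- match(tab$traffic_load, c(25, 35, 45, 55))
  tab$value <- tab$value + ifelse(tab$cluster == "sensitive", 10, 1) * lvl
  m <- mixed_anova(tab)
  Y <- matrix(NA, 21, 8)
  k <- 0
  for (p in c(FALSE, TRUE)) for (l in c(25, 35, 45, 55)) {
    k <- k + 1
    sel <- tab$priority == p & tab$traffic_load == l
    Y[, k] <- tab$value[sel][order(tab$subject[sel])]
  }
  g <- factor(cl)
  av <- suppressWarnings(
    summary(car::Anova(stats::lm(Y ~ g, contrasts = list(g = stats::contr.sum)),
                       idata = data.frame(load = factor(rep(c(25, 35, 45, 55), 2)),
                                          prio = factor(rep(0:1, each = 4))),
                       idesign = ~ load * prio, type = 3),
            multivariate = FALSE))
  ref <- av$univariate.tests
  ours <- m$table
  pick <- function(eff) ours$F[ours$effect == eff]
  expect_equal(pick("cluster"), unname(ref["g", "F value"]))
  expect_equal(pick("traffic_load"), unname(ref["load", "F value"]))
  expect_equal(pick("traffic_load:cluster"), unname(ref["g:load", "F value"]))
  expect_equal(pick("priority:cluster"), unname(ref["g:prio", "F value"]))
  expect_equal(pick("traffic_load:priority:cluster"),
               unname(ref["g:load:prio", "F value"]))
  # the planted cluster-by-load interaction is detected
  expect_lt(ours$p[ours$effect == "traffic_load:cluster"], 0.01)
  # relabelling clusters leaves the interaction F unchanged
  tab2 <- tab
  tab2$cluster <- ifelse(tab$cluster == "sensitive", "not", "sensitive")
  m2 <- mixed_anova(tab2)
  expect_equal(m2$table$F, m$table$F)
  # identical condition profiles in both clusters: interaction F ~ 0
  flat <- make_condition_table(n = 10, load_shift = 5, cluster = rep(c("a", "b"), 5))
  mf <- mixed_anova(flat)
  expect_equal(mf$table$F[mf$table$effect == "traffic_load:cluster"], 0,
               tolerance = 1e-20)
  expect_error(mixed_anova(make_condition_table(n = 3,
                                                cluster = c("a", "a", "b"))),
               ">= 2 subjects")
})

test_that("same-load correlations match the ICC of a shared subject effect", {
  expect_equal(same_load_correlation(
    make_condition_table(n = 10, subj_sd = 8, noise_sd = 0, seed = 3))$r,
    rep(1, 4))
  # negated pairing gives r = -1
  tab <- make_condition_table(n = 10, subj_sd = 8, noise_sd = 0, seed = 3)
  tab$value[tab$priority] <- 60 - tab$value[tab$priority]
  expect_equal(same_load_correlation(tab)$r, rep(-1, 4))
  # closed-form oracle: r -> sigma_s^2 / (sigma_s^2 + sigma_n^2) = 0.8
  big <- make_condition_table(n = 400, subj_sd = 10, noise_sd = 5, seed = 17)
  r <- same_load_correlation(big)$r
  expect_true(all(abs(r - 0.8) < 0.15))
  degen <- make_condition_table(n = 5)
  expect_error(same_load_correlation(degen), "zero variance")
})
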