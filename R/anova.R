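# Validation statistics for the 2 (priority-flight request) x 4 (traffic
# load) within-subject design: Pearson reliability correlations, two-way
# repeated-measures ANOVA with Mauchly sphericity test and Greenhouse-
# Geisser correction, mixed ANOVA with a between-subject cluster factor,
# and Bonferroni-corrected paired post-hoc comparisons.

# Orthonormal contrast matrix (k x k-1), columns orthogonal to the constant.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

# Mauchly's test and Greenhouse-Geisser epsilon from an n x p matrix of
# within-subject contrast scores; df_err is the covariance df (n-1 in the
# single-group design, N-groups in the mixed design, where S is then the
# pooled within-group covariance).
mauchly_gg <- function(S, df_err) {
  p <- ncol(S)
  eps <- sum(diag(S))^2 / (p * sum(S^2))
  if (!is.finite(eps)) eps <- 1          # zero-variance scores
  W <- det(S) / (sum(diag(S)) / p)^p
  if (!is.finite(W) || W <= 0) {
    return(list(W = NA_real_, p = NA_real_, eps = max(eps, 1 / p)))
  }
  chisq <- -(df_err - (2 * p^2 + p + 2) / (6 * p)) * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chisq, df, lower.tail = FALSE), eps = eps)
}

# Validate and reshape a condition table into a subject x load x priority
# array; exactly one value per cell is required (no imputation).
condition_array <- function(table) {
  needed <- c("subject", "traffic_load", "priority", "value")
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0) stop_dfhm("condition table misses columns: ",
                                  paste(miss, collapse = ", "))
  subj <- factor(table$subject)
  load <- factor(table$traffic_load)
  prio <- factor(table$priority)
  counts <- base::table(subj, load, prio)
  if (any(counts != 1)) {
    stop_dfhm("incomplete or duplicated cells: each subject needs exactly ",
              "one value per traffic_load x priority cell")
  }
  y <- tapply(table$value, list(subj, load, prio), identity)
  array(unlist(y), dim = dim(y), dimnames = dimnames(y))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for the complete balanced subject x traffic-load x
#' priority design.  Each within effect is tested against its own
#' effect-by-subject error term; Mauchly's sphericity test is run on the
#' orthonormal contrast scores of every effect with more than one degree of
#' freedom, and when it is significant at the 0.05 level the
#' Greenhouse-Geisser epsilon is applied to the degrees of freedom (the
#' reported p is then the corrected one).  Partial eta squared is
#' SS_effect / (SS_effect + SS_error).
#'
#' @param table data frame with columns \code{subject},
#'   \code{traffic_load}, \code{priority}, \code{value}; complete crossing,
#'   one value per cell
#' @param mauchly_alpha significance level triggering the GG correction;
#'   default 0.05
#' @return object of class \code{dfhm_anova}: list with \code{table} (data
#'   frame: effect, df1, df2, SS, SS_error, F, eps, gg_applied, p,
#'   p_uncorrected, peta2), \code{mauchly}, and \code{ss} (all sums of
#'   squares incl. subject and total, for the decomposition identity)
#' @export
rm_anova_2way <- function(table, mauchly_alpha = 0.05) {
  y <- condition_array(table)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2) stop_dfhm("need >= 2 subjects")
  m <- mean(y)
  m_s <- apply(y, 1, mean)
  m_i <- apply(y, 2, mean)
  m_j <- apply(y, 3, mean)
  m_si <- apply(y, c(1, 2), mean)
  m_sj <- apply(y, c(1, 3), mean)
  m_ij <- apply(y, c(2, 3), mean)

  ss_s <- a * b * sum((m_s - m)^2)
  ss_a <- n * b * sum((m_i - m)^2)
  ss_b <- n * a * sum((m_j - m)^2)
  ss_ab <- n * sum((m_ij - outer(m_i, rep(1, b)) - outer(rep(1, a), m_j) + m)^2)
  ss_as <- b * sum((m_si - outer(m_s, rep(1, a)) - outer(rep(1, n), m_i) + m)^2)
  ss_bs <- a * sum((m_sj - outer(m_s, rep(1, b)) - outer(rep(1, n), m_j) + m)^2)
  ss_t <- sum((y - m)^2)
  ss_abs <- ss_t - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  C_a <- orthonormal_contrasts(a)
  C_b <- orthonormal_contrasts(b)
  sph_a <- mauchly_gg(stats::cov(m_si %*% C_a), n - 1)
  Yflat <- matrix(y, nrow = n)               # columns: (i, j) with i fastest
  K_ab <- kronecker(C_b, C_a)
  sph_ab <- mauchly_gg(stats::cov(Yflat %*% K_ab), n - 1)
  sph_b <- list(W = NA_real_, p = NA_real_, eps = 1)

  mk_row <- function(effect, ss, ss_err, df1, df2, sph) {
    f <- if (ss == 0) 0 else (ss / df1) / (ss_err / df2)  # 0/0 reads as no effect
    gg <- is.finite(sph$p) && sph$p < mauchly_alpha
    p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)
    p <- if (gg) stats::pf(f, df1 * sph$eps, df2 * sph$eps, lower.tail = FALSE) else p_unc
    data.frame(effect = effect, df1 = df1, df2 = df2, SS = ss,
               SS_error = ss_err, F = f, eps = sph$eps, gg_applied = gg,
               p = p, p_uncorrected = p_unc,
               peta2 = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
  }
  tab <- rbind(
    mk_row("traffic_load", ss_a, ss_as, a - 1, (a - 1) * (n - 1), sph_a),
    mk_row("priority", ss_b, ss_bs, b - 1, (b - 1) * (n - 1), sph_b),
    mk_row("traffic_load:priority", ss_ab, ss_abs, (a - 1) * (b - 1),
           (a - 1) * (b - 1) * (n - 1), sph_ab))
  structure(list(table = tab,
                 mauchly = list(traffic_load = sph_a,
                                `traffic_load:priority` = sph_ab),
                 ss = list(subject = ss_s, traffic_load = ss_a,
                           priority = ss_b, interaction = ss_ab,
                           load_x_subject = ss_as, priority_x_subject = ss_bs,
                           residual = ss_abs, total = ss_t)),
            class = "dfhm_anova")
}

#' @export
print.dfhm_anova <- function(x, digits = 4, ...) {
  cat("<dfhm_anova>\n")
  tab <- x$table
  tab$SS <- signif(tab$SS, digits)
  tab$SS_error <- signif(tab$SS_error, digits)
  tab$F <- signif(tab$F, digits)
  tab$eps <- round(tab$eps, 3)
  tab$p <- signif(tab$p, 3)
  tab$p_uncorrected <- signif(tab$p_uncorrected, 3)
  tab$peta2 <- round(tab$peta2, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Mixed ANOVA with a between-subject cluster factor
#'
#' Split-plot ANOVA: cluster affiliation (e.g. workload sensitive vs. not
#' sensitive) as between-subject factor, traffic load and priority as
#' within-subject factors.  Within effects and their cluster interactions
#' are computed on orthonormal contrast scores and tested against the
#' pooled within-group error; Greenhouse-Geisser correction is applied as
#' in \code{\link{rm_anova_2way}}.
#'
#' @param table condition table as in \code{\link{rm_anova_2way}} plus a
#'   \code{cluster} column; every cluster needs >= 2 subjects with complete
#'   within-subject tables
#' @param mauchly_alpha level triggering the GG correction
#' @return a \code{dfhm_anova} whose table holds the between effect, the
#'   within effects and all cluster interactions
#' @export
mixed_anova <- function(table, mauchly_alpha = 0.05) {
  if (!"cluster" %in% names(table)) stop_dfhm("table needs a cluster column")
  y <- condition_array(table)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  cl <- table[!duplicated(table$subject), c("subject", "cluster")]
  grp <- factor(cl$cluster[match(dimnames(y)[[1]], as.character(cl$subject))])
  if (nlevels(grp) < 2) stop_dfhm("need >= 2 clusters")
  nk <- base::table(grp)
  if (any(nk < 2)) stop_dfhm("every cluster needs >= 2 subjects")
  g <- nlevels(grp)
  N <- n
  cells <- a * b

  # between-subject part, on per-subject means
  t_s <- apply(y, 1, mean)
  m_k <- tapply(t_s, grp, mean)
  m_w <- mean(t_s)
  ss_g <- cells * sum(nk * (m_k - m_w)^2)
  ss_sg <- cells * sum((t_s - m_k[grp])^2)
  f_g <- if (ss_g == 0) 0 else (ss_g / (g - 1)) / (ss_sg / (N - g))

  # within-subject effects on contrast scores
  C_a <- orthonormal_contrasts(a)
  C_b <- orthonormal_contrasts(b)
  score_sets <- list(
    traffic_load = list(Z = apply(y, c(1, 2), mean) %*% C_a, mult = b),
    priority = list(Z = apply(y, c(1, 3), mean) %*% C_b, mult = a),
    `traffic_load:priority` = list(Z = matrix(y, nrow = n) %*% kronecker(C_b, C_a),
                                   mult = 1))
  harm <- g^2 / sum(1 / nk)           # unweighted (type III) main effects
  rows <- list(data.frame(effect = "cluster", df1 = g - 1, df2 = N - g,
                          SS = ss_g, SS_error = ss_sg, F = f_g, eps = 1,
                          gg_applied = FALSE,
                          p = stats::pf(f_g, g - 1, N - g, lower.tail = FALSE),
                          p_uncorrected = stats::pf(f_g, g - 1, N - g,
                                                    lower.tail = FALSE),
                          peta2 = ss_g / (ss_g + ss_sg)))
  mauchly <- list()
  for (nm in names(score_sets)) {
    Z <- score_sets[[nm]]$Z
    mult <- score_sets[[nm]]$mult
    p_dim <- ncol(Z)
    gm_k <- apply(Z, 2, function(zc) tapply(zc, grp, mean))  # g x p
    if (p_dim == 1) gm_k <- matrix(gm_k, ncol = 1)
    u_bar <- colMeans(gm_k)                                  # unweighted
    w_bar <- colMeans(Z)
    ss_e <- mult * harm * sum(u_bar^2)
    ss_exg <- mult * sum(vapply(seq_len(p_dim), function(d) {
      sum(nk * (gm_k[, d] - w_bar[d])^2)
    }, numeric(1)))
    resid <- Z - gm_k[grp, , drop = FALSE]
    ss_err <- mult * sum(resid^2)
    # pooled within-group covariance for sphericity
    S_pool <- matrix(0, p_dim, p_dim)
    for (k in levels(grp)) {
      Zk <- Z[grp == k, , drop = FALSE]
      S_pool <- S_pool + (nrow(Zk) - 1) * stats::cov(Zk)
    }
    S_pool <- S_pool / (N - g)
    sph <- if (p_dim > 1) mauchly_gg(S_pool, N - g) else
      list(W = NA_real_, p = NA_real_, eps = 1)
    mauchly[[nm]] <- sph
    gg <- is.finite(sph$p) && sph$p < mauchly_alpha
    mk <- function(effect, ss, df1) {
      df2 <- p_dim * (N - g)
      f <- if (ss == 0) 0 else (ss / df1) / (ss_err / df2)
      p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)
      pp <- if (gg) stats::pf(f, df1 * sph$eps, df2 * sph$eps,
                              lower.tail = FALSE) else p_unc
      data.frame(effect = effect, df1 = df1, df2 = df2, SS = ss,
                 SS_error = ss_err, F = f, eps = sph$eps, gg_applied = gg,
                 p = pp, p_uncorrected = p_unc,
                 peta2 = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
    }
    rows <- c(rows, list(mk(nm, ss_e, p_dim),
                         mk(paste0(nm, ":cluster"), ss_exg, p_dim * (g - 1))))
  }
  structure(list(table = do.call(rbind, rows), mauchly = mauchly,
                 ss = list(between = ss_g, between_error = ss_sg)),
            class = "dfhm_anova")
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Paired t tests on the per-subject level means of one within factor
#' (collapsed over the other), with p multiplied by the number of pairwise
#' comparisons and capped at 1.
#'
#' @param table condition table as in \code{\link{rm_anova_2way}}
#' @param effect \code{"traffic_load"} or \code{"priority"}
#' @return data frame with one row per level pair: levels, mean difference,
#'   t, df, p, p_adjusted
#' @export
bonferroni_posthoc <- function(table, effect = c("traffic_load", "priority")) {
  effect <- match.arg(effect)
  y <- condition_array(table)
  M <- if (effect == "traffic_load") apply(y, c(1, 2), mean) else apply(y, c(1, 3), mean)
  lev <- colnames(M)
  pairs <- utils::combn(seq_along(lev), 2)
  n_cmp <- ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    d <- M[, pr[1]] - M[, pr[2]]
    if (stats::sd(d) == 0) {      # identical levels: no evidence against H0
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(d)
    }
    data.frame(level1 = lev[pr[1]], level2 = lev[pr[2]],
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_adjusted = min(1, tt$p.value * n_cmp))
  })
  do.call(rbind, rows)
}

#' Pearson reliability correlations between same-load scenario pairs
#'
#' For every traffic-load level, the per-subject first-5-min index means of
#' the scenario without the priority event are correlated with those of the
#' scenario with the event.
#'
#' @param first5 data frame with columns \code{subject},
#'   \code{traffic_load}, \code{priority} (logical/2-level), \code{value}
#'   (slot-mean DFHM index); both scenarios of each load must be present
#'   for every subject
#' @return data frame with one row per load: \code{traffic_load}, \code{r},
#'   \code{p}, \code{n}
#' @export
same_load_correlation <- function(first5) {
  y <- condition_array(first5)
  loads <- dimnames(y)[[2]]
  rows <- lapply(seq_along(loads), function(i) {
    x1 <- y[, i, 1]
    x2 <- y[, i, 2]
    if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
      stop_dfhm("zero variance at traffic load ", loads[i])
    }
    ct <- stats::cor.test(x1, x2)
    data.frame(traffic_load = loads[i], r = unname(ct$estimate),
               p = ct$p.value, n = length(x1))
  })
  do.call(rbind, rows)
}
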