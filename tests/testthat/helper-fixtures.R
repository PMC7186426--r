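# Shared fixtures, built in code at test time.

MONT <- default_montage()

# single- or multi-channel recording of pure sinusoids
sine_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 500,
                           duration = 10,
                           channels = MONT$electrode_names[seq_along(freqs)]) {
  t <- (seq_len(fs * duration) - 1) / fs
  data <- t(vapply(seq_along(freqs),
                   function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                   numeric(length(t))))
  eeg_recording(data, fs, channels)
}

# exhaustive exact distribution of the signed-rank statistic W+ for n
# untied differences: the independent oracle for the normal approximation
exact_signed_rank_cdf <- function(n) {
  w <- 0:(n * (n + 1) / 2)
  counts <- numeric(length(w))
  for (m in 0:(2^n - 1)) {
    s <- sum(which(bitwAnd(m, 2^(0:(n - 1))) > 0))
    counts[s + 1] <- counts[s + 1] + 1
  }
  cumsum(counts) / 2^n
}

# balanced within-subject condition table with planted effects
make_condition_table <- function(n = 12, load_shift = 0, prio_shift = 0,
                                 subj_sd = 0, noise_sd = 0, seed = 1,
                                 cluster = NULL) {
  withr::with_seed(seed, {
    tab <- expand.grid(subject = seq_len(n),
                       traffic_load = c(25, 35, 45, 55),
                       priority = c(FALSE, TRUE))
    lvl <- match(tab$traffic_load, c(25, 35, 45, 55))
    subj_eff <- stats::rnorm(n, 0, subj_sd)
    tab$value <- 30 + load_shift * lvl + prio_shift * tab$priority +
      subj_eff[tab$subject] + stats::rnorm(nrow(tab), 0, noise_sd)
    if (!is.null(cluster)) tab$cluster <- cluster[tab$subject]
    tab
  })
}
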