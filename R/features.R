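#' Cut a recording into 1-s segments overlapping by 0.5 s
#'
#' Segments start at 0.0, 0.5, 1.0, ... seconds; only segments with full
#' one-second support are kept (trailing partial data are dropped), so a
#' recording of T whole seconds yields \code{2*T - 1} segments -- 119 for a
#' 60-s recording.
#'
#' @param rec an \code{eeg_recording} of at least 1 s
#' @return object of class \code{segment_set}: the data matrix plus
#'   \code{start_times} (s), \code{fs} and channel names
#' @export
segment_recording <- function(rec) {
  n <- ncol(rec$data)
  fs <- rec$fs
  if (n < fs) stop_dfhm("recording shorter than one segment (1 s)")
  n_seg <- floor(2 * n / fs) - 1
  starts <- 0.5 * (seq_len(n_seg) - 1)
  structure(list(data = rec$data, fs = fs, start_times = starts,
                 channel_names = rec$channel_names),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", length(x$start_times), " segments of 1 s (",
      length(x$channel_names), " channels @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' FFT band power per segment and electrode
#'
#' For each 1-s segment the one-sided periodogram is computed with a
#' rectangular window and scaled so that the sum over all frequency bins
#' equals the mean squared signal (Parseval); band power is the sum over
#' bins with frequency in the half-open interval \code{[band[1], band[2])}
#' Hz.  At 500 Hz and 1-s segments the bin spacing is 1 Hz, so a pure
#' sinusoid of amplitude a at an integer in-band frequency yields a^2/2.
#' The half-open convention assigns the 8 Hz bin to alpha, not theta.
#'
#' @param segs a \code{segment_set}
#' @param band numeric length-2, band edges in Hz within (0, fs/2)
#' @return object of class \code{band_power_matrix}: \code{values}
#'   (segments x electrodes, uV^2), \code{band}, \code{start_times}
#' @export
band_power <- function(segs, band) {
  band_power_multi(segs, list(band))[[1]]
}

#' Band power for several bands in one periodogram pass
#'
#' Computes the per-segment periodograms once and extracts every requested
#' band, which halves the cost of the theta + alpha extraction.
#'
#' @param segs a \code{segment_set}
#' @param bands list of length-2 band-edge vectors
#' @return list of \code{band_power_matrix} objects, one per band
#' @export
band_power_multi <- function(segs, bands) {
  fs <- segs$fs
  nfft <- fs                       # 1-s segments
  freqs <- 0:(nfft %/% 2)
  sels <- lapply(bands, function(band) {
    if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= fs / 2)) {
      stop_dfhm("band outside (0, fs/2)")
    }
    # half-open band [lo, hi); the Nyquist edge is inclusive so that the
    # full band [0, fs/2] satisfies the Parseval identity exactly
    sel <- which(freqs >= band[1] &
                   (freqs < band[2] | (band[2] == fs / 2 & freqs == band[2])))
    if (length(sel) == 0) stop_dfhm("band contains no FFT bins")
    sel
  })
  k <- length(segs$start_times)
  idx0 <- round(segs$start_times * fs)
  cols <- as.vector(outer(seq_len(nfft), idx0, `+`))   # segment sample index
  mid <- freqs > 0 & freqs < nfft / 2
  values <- lapply(bands, function(b) {
    matrix(0, k, length(segs$channel_names),
           dimnames = list(NULL, segs$channel_names))
  })
  for (ch in seq_along(segs$channel_names)) {
    M <- matrix(segs$data[ch, cols], nrow = nfft)       # nfft x k
    P <- abs(stats::mvfft(M))^2 / nfft^2                # two-sided, sums to msq
    one_sided <- P[freqs + 1, , drop = FALSE]
    one_sided[mid, ] <- one_sided[mid, ] + P[nfft + 1 - freqs[mid], , drop = FALSE]
    for (bi in seq_along(bands)) {
      values[[bi]][, ch] <- colSums(one_sided[sels[[bi]], , drop = FALSE])
    }
  }
  lapply(seq_along(bands), function(bi) {
    structure(list(values = values[[bi]], band = bands[[bi]],
                   start_times = segs$start_times),
              class = "band_power_matrix")
  })
}

#' Per-electrode baseline statistics from the first minute
#'
#' Mean and standard deviation of band power over the segments fully
#' contained in the first \code{baseline_end} seconds of the scenario
#' (start time <= baseline_end - 1 s), i.e. 119 segments for the default
#' 60-s baseline.  These personalize the z-scores: every subject and
#' scenario is scaled against its own quiet first minute.
#'
#' @param bp a \code{band_power_matrix}
#' @param baseline_end end of the baseline window in seconds; default 60
#' @return object of class \code{baseline_stats} with per-electrode
#'   \code{mean}, \code{sd} and \code{n_segments}
#' @export
baseline_stats <- function(bp, baseline_end = 60) {
  in_base <- bp$start_times <= baseline_end - 1
  if (sum(in_base) < 2) stop_dfhm("fewer than 2 baseline segments")
  v <- bp$values[in_base, , drop = FALSE]
  m <- colMeans(v)
  s <- apply(v, 2, stats::sd)
  if (any(s == 0)) {
    stop_dfhm("degenerate baseline: zero band-power variance on ",
              paste(colnames(v)[s == 0], collapse = ", "))
  }
  structure(list(mean = m, sd = s, n_segments = sum(in_base)),
            class = "baseline_stats")
}

#' z-score band powers against baseline statistics
#'
#' @param bp a \code{band_power_matrix}
#' @param stats a \code{baseline_stats} covering all electrodes of \code{bp}
#' @return a \code{band_power_matrix} in z-units (same structure)
#' @export
zscore_band_power <- function(bp, stats) {
  el <- colnames(bp$values)
  missing_el <- setdiff(el, names(stats$mean))
  if (length(missing_el) > 0) {
    stop_dfhm("no baseline statistics for: ", paste(missing_el, collapse = ", "))
  }
  z <- sweep(sweep(bp$values, 2, stats$mean[el]), 2, stats$sd[el], `/`)
  structure(list(values = z, band = bp$band, start_times = bp$start_times,
                 units = "z"),
            class = "band_power_matrix")
}

#' Assemble Dual Frequency Head Maps
#'
#' One DFHM per segment: the z-scored theta power at each frontal electrode
#' followed by the z-scored alpha power at each parietal electrode, in
#' montage order.  The fixed feature ordering (recorded in
#' \code{feature_names}) is the contract shared with the classifier.
#'
#' @param z_theta,z_alpha z-scored \code{band_power_matrix} objects on the
#'   same segment grid
#' @param montage a \code{dfhm_montage} supplying the frontal and parietal
#'   electrode sets and their order
#' @return object of class \code{dfhm_features}: \code{features} (segments x
#'   features matrix), \code{feature_names}, \code{times} (segment start
#'   times, s)
#' @export
build_dfhm <- function(z_theta, z_alpha, montage = default_montage()) {
  if (!isTRUE(all.equal(z_theta$start_times, z_alpha$start_times))) {
    stop_dfhm("theta and alpha matrices are on different segment grids")
  }
  fr <- frontal_electrodes(montage)
  pa <- parietal_electrodes(montage)
  feat <- cbind(z_theta$values[, fr, drop = FALSE],
                z_alpha$values[, pa, drop = FALSE])
  nm <- c(paste0(fr, ".theta"), paste0(pa, ".alpha"))
  colnames(feat) <- nm
  structure(list(features = feat, feature_names = nm,
                 times = z_theta$start_times),
            class = "dfhm_features")
}

#' @export
print.dfhm_features <- function(x, ...) {
  cat("<dfhm_features> ", nrow(x$features), " segments x ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Export DFHM features as a long-format CSV
#'
#' Columns \code{segment_time}, \code{feature_name}, \code{value}; feature
#' names are stored with every export so a classifier can verify
#' compatibility.
#'
#' @param feats a \code{dfhm_features}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_dfhm_csv <- function(feats, path) {
  long <- data.frame(
    segment_time = rep(feats$times, times = length(feats$feature_names)),
    feature_name = rep(feats$feature_names, each = length(feats$times)),
    value = as.vector(feats$features))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dfhm_csv
#' @export
read_dfhm_csv <- function(path) {
  long <- utils::read.csv(path)
  nm <- unique(long$feature_name)
  times <- unique(long$segment_time)
  feat <- matrix(long$value, nrow = length(times), ncol = length(nm),
                 dimnames = list(NULL, nm))
  structure(list(features = feat, feature_names = nm, times = times),
            class = "dfhm_features")
}
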