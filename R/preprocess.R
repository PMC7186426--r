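#' Linear-phase FIR bandpass filter
#'
#' Applies a Hamming-window linear-phase FIR bandpass of the given order to
#' every channel.  The filter's constant group delay of \code{order/2}
#' samples is compensated by shifting the output back, so band-interior
#' oscillations keep their phase; the default 0.5--40 Hz order-100 design is
#' the conditioning step used ahead of ICA artifact rejection.
#'
#' @param rec an \code{eeg_recording}
#' @param low,high band edges in Hz, \code{0 < low < high < fs/2}
#' @param order FIR filter order (number of taps minus one); default 100
#' @return filtered \code{eeg_recording} of identical shape and rate
#' @export
bandpass <- function(rec, low = 0.5, high = 40, order = 100) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_dfhm("band (", low, ", ", high, ") Hz outside (0, fs/2) = (0, ",
              fs / 2, ")")
  }
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  delay <- order / 2
  n <- ncol(rec$data)
  # FFT convolution of all channels at once (columns of an L x nch matrix)
  L <- stats::nextn(n + order, c(2, 3, 5))
  H <- stats::fft(c(b, rep(0, L - length(b))))
  X <- matrix(0, L, nrow(rec$data))
  X[seq_len(n), ] <- t(rec$data)
  Y <- stats::mvfft(stats::mvfft(X) * H, inverse = TRUE) / L
  rec$data <- t(Re(Y[(delay + 1):(delay + n), , drop = FALSE]))
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Hjorth-style surface Laplacian
#'
#' Replaces each channel by its value minus the unweighted mean of its
#' available neighbours in the montage -- a spatial high-pass that attenuates
#' broad scalp signals and sharpens local sources.  The reference tag is set
#' to \code{"laplacian"}.
#'
#' @param rec an \code{eeg_recording} whose channels all appear in
#'   \code{montage}
#' @param montage a \code{dfhm_montage}
#' @return Laplacian-filtered \code{eeg_recording}
#' @export
hjorth_laplacian <- function(rec, montage = default_montage()) {
  missing_ch <- setdiff(rec$channel_names, montage$electrode_names)
  if (length(missing_ch) > 0) {
    stop_dfhm("channels not in montage: ", paste(missing_ch, collapse = ", "))
  }
  nch <- length(rec$channel_names)
  lap <- diag(nch)
  dimnames(lap) <- list(rec$channel_names, rec$channel_names)
  for (ch in rec$channel_names) {
    nb <- intersect(montage$neighbor_map[[ch]], rec$channel_names)
    if (length(nb) == 0) {
      stop_dfhm("channel ", ch, " has no neighbors among recorded channels")
    }
    lap[ch, nb] <- -1 / length(nb)
  }
  rec$data <- lap %*% rec$data
  rec$reference <- "laplacian"
  rec
}

#' Average re-referencing
#'
#' Subtracts the per-sample mean over channels from every channel; the
#' reference tag becomes \code{"average"}.
#'
#' @param rec an \code{eeg_recording} with at least two channels
#' @return re-referenced \code{eeg_recording}
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) {
    stop_dfhm("average reference needs at least 2 channels")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  rec
}
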