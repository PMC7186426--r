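# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a 256-byte ASCII global header, one 256-byte ASCII header per
# signal, and the samples as little-endian 16-bit integers mapped linearly
# between a digital and a physical range.  This implementation covers
# continuous equal-rate multichannel recordings, which is all the workload
# pipeline needs; events travel in a sidecar CSV (columns label,time_s)
# written next to the EDF, since annotation (EDF+ TAL) channels are out of
# scope here.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

events_sidecar_path <- function(path) {
  paste0(sub("\\.edf$", "", path, ignore.case = TRUE), ".events.csv")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' derived from the data, so a read-back recording agrees with the original
#' to within one quantization step.  Events, if any, are written to a
#' sidecar CSV \code{<path-without-.edf>.events.csv} with columns
#' \code{label,time_s}.
#'
#' @param rec an \code{eeg_recording}
#' @param path output path (conventionally ending in \code{.edf})
#' @return \code{path}, invisibly
#' @export
write_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  amax <- max(abs(rec$data), 1e-6)
  phys_min <- -amax
  phys_max <- amax
  dig_min <- -32768L
  dig_max <- 32767L
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((rec$data - phys_min) / scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X X ref", rec$reference), 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + n_ch), 8),
    edf_pad("", 44),
    edf_pad(1, 8),                       # one data record holding everything
    edf_pad(format(n_samp / rec$fs, digits = 8), 8),
    edf_pad(n_ch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("", 80), n_ch),
    rep(edf_pad("uV", 8), n_ch),
    rep(edf_pad(format(phys_min, digits = 7), 8), n_ch),
    rep(edf_pad(format(phys_max, digits = 7), 8), n_ch),
    rep(edf_pad(dig_min, 8), n_ch),
    rep(edf_pad(dig_max, 8), n_ch),
    rep(edf_pad("", 80), n_ch),
    rep(edf_pad(n_samp, 8), n_ch),
    rep(edf_pad("", 32), n_ch)
  )
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
  # one record: all samples of signal 1, then all of signal 2, ...
  writeBin(as.vector(t(dig)), con, size = 2, endian = "little")

  if (nrow(rec$events) > 0) {
    utils::write.csv(
      data.frame(label = rec$events$label, time_s = rec$events$time),
      events_sidecar_path(path), row.names = FALSE)
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  h <- list()
  version <- rd(8)
  if (!grepl("^0", version)) stop_dfhm("not an EDF file (bad version field)")
  rd(80); h$recording_id <- rd(80); rd(8); rd(8)
  h$header_bytes <- as.integer(rd(8)); rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_duration <- as.numeric(rd(8))
  h$n_signals <- as.integer(rd(4))
  ns <- h$n_signals
  if (is.na(ns) || ns < 1) stop_dfhm("not an EDF file (bad signal count)")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- trimws(rdv(16)); rdv(80); rdv(8)
  h$phys_min <- as.numeric(rdv(8)); h$phys_max <- as.numeric(rdv(8))
  h$dig_min <- as.numeric(rdv(8)); h$dig_max <- as.numeric(rdv(8))
  rdv(80)
  h$samples_per_record <- as.integer(rdv(8)); rdv(32)
  h
}

#' Load an EEG recording from an EDF file
#'
#' @param path path to an EDF file
#' @param montage a \code{dfhm_montage} the channel labels must resolve
#'   against; pass \code{NULL} to skip the check
#' @return an \code{eeg_recording}; events are read from the sidecar CSV
#'   \code{<path-without-.edf>.events.csv} when present
#' @export
load_recording <- function(path, montage = default_montage()) {
  if (!file.exists(path)) stop_dfhm("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(read_edf_header(con),
                error = function(e) stop_dfhm("unreadable EDF file: ",
                                              conditionMessage(e)))
  ns <- h$n_signals
  spr <- h$samples_per_record
  if (any(is.na(spr)) || any(spr <= 0) || is.na(h$n_records)) {
    stop_dfhm("unreadable EDF file: corrupt signal headers")
  }
  scale <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  data <- matrix(0, nrow = ns, ncol = spr[1] * h$n_records)
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[s]) stop_dfhm("unreadable EDF file: truncated data")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        h$phys_min[s] + (raw - h$dig_min[s]) * scale[s]
    }
  }
  if (!is.null(montage)) {
    unknown <- setdiff(h$labels, montage$electrode_names)
    if (length(unknown) > 0) {
      stop_dfhm("channel labels not in montage: ",
                paste(unknown, collapse = ", "))
    }
  }
  fs <- spr[1] / h$record_duration * 1  # equal rates assumed
  ref <- sub(".*ref ", "", trimws(h$recording_id))
  if (identical(ref, trimws(h$recording_id)) || nchar(ref) == 0) ref <- "unknown"
  ev_path <- events_sidecar_path(path)
  events <- NULL
  if (file.exists(ev_path)) {
    df <- utils::read.csv(ev_path)
    events <- data.frame(label = df$label, time = df$time_s)
  }
  eeg_recording(data, fs, h$labels, reference = ref, events = events)
}
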