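#' Construct an EEG recording object
#'
#' A recording is a channels-by-samples matrix in microvolts with a sampling
#' rate, channel labels, a reference tag and an event table.  The reference
#' tag tracks the preprocessing state: raw recordings referenced to an
#' electrode (e.g. \code{"Cz"}), \code{"laplacian"} after the surface
#' Laplacian, \code{"average"} after average re-referencing.
#'
#' @param data numeric matrix, channels x samples, in microvolts
#' @param fs sampling rate in Hz
#' @param channel_names character vector matching \code{nrow(data)}
#' @param reference reference label; default \code{"Cz"}
#' @param events data frame with columns \code{label} and \code{time}
#'   (seconds from recording start, non-negative and non-decreasing), or
#'   \code{NULL}
#' @return object of class \code{eeg_recording}
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          reference = "Cz", events = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    stop_dfhm("channel_names are required")
  }
  if (nrow(data) != length(channel_names)) {
    stop_dfhm("data has ", nrow(data), " rows but ", length(channel_names),
              " channel names")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_dfhm("fs must be a single positive number")
  }
  if (!all(is.finite(data))) {
    stop_dfhm("recording contains non-finite samples")
  }
  events <- validate_events(events)
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 reference = reference, events = events),
            class = "eeg_recording")
}

validate_events <- function(events) {
  if (is.null(events)) {
    return(data.frame(label = character(0), time = numeric(0)))
  }
  events <- as.data.frame(events)
  stopifnot(all(c("label", "time") %in% names(events)))
  events$label <- as.character(events$label)
  events$time <- as.numeric(events$time)
  if (any(events$time < 0)) stop_dfhm("event times must be non-negative")
  if (is.unsorted(events$time)) stop_dfhm("event times must be non-decreasing")
  events[, c("label", "time")]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1),
      " s), reference: ", x$reference, ", ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an \code{eeg_recording}
#' @return duration in seconds
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' First event time matching a label
#'
#' Returns the time (seconds from recording start) of the earliest event
#' whose label equals \code{label}, or \code{NA_real_} when no such event
#' exists -- scenarios without a priority-flight request legitimately carry
#' no trigger, so absence is a valid outcome, not an error.
#'
#' @param rec an \code{eeg_recording}
#' @param label event label to search for
#' @return time in seconds, or \code{NA_real_}
#' @export
extract_event_time <- function(rec, label) {
  hit <- rec$events$time[rec$events$label == label]
  if (length(hit) == 0) NA_real_ else min(hit)
}
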