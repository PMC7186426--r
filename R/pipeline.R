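# End-to-end orchestration: configuration, the preprocessing chain in its
# fixed order (bandpass -> ICA rejection -> surface Laplacian -> average
# reference), feature extraction, classification and the workload index.

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: 0.5-40 Hz order-100 bandpass,
#' Infomax ICA with the automatic rejection policy, Hjorth Laplacian,
#' average reference, 1-s segments overlapping by 0.5 s, theta 4-8 Hz and
#' alpha 8-12 Hz, 60-s baseline for the personalized z-scores and the 30-s
#' (60-value) index window.
#'
#' @param band bandpass edges in Hz
#' @param filter_order FIR order
#' @param ica run ICA artifact rejection?  Disable for artifact-free
#'   synthetic data where it only costs time.
#' @param ica_policy rejection policy (see
#'   \code{\link{auto_rejection_policy}})
#' @param ica_seed seed for the ICA fit
#' @param theta,alpha band definitions in Hz
#' @param baseline_end baseline length in seconds
#' @param montage a \code{dfhm_montage}
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(band = c(0.5, 40), filter_order = 100,
                            ica = TRUE, ica_policy = auto_rejection_policy(),
                            ica_seed = 1, theta = c(4, 8), alpha = c(8, 12),
                            baseline_end = 60, montage = default_montage()) {
  structure(list(band = band, filter_order = filter_order, ica = ica,
                 ica_policy = ica_policy, ica_seed = ica_seed,
                 theta = theta, alpha = alpha, baseline_end = baseline_end,
                 montage = montage),
            class = "pipeline_config")
}

# 31-bit polynomial rolling hash of the deparsed config, hex string.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Preprocess a recording for DFHM analysis
#'
#' Runs the conditioning chain in its fixed order: bandpass filter, ICA
#' artifact rejection (optional), Hjorth surface Laplacian, average
#' re-referencing.
#'
#' @param rec a raw \code{eeg_recording}
#' @param config a \code{pipeline_config}
#' @return preprocessed \code{eeg_recording} (reference tag
#'   \code{"average"})
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  rec <- bandpass(rec, config$band[1], config$band[2], config$filter_order)
  if (isTRUE(config$ica)) {
    decomp <- fit_ica(rec, seed = config$ica_seed)
    rec <- reject_components(rec, decomp, config$ica_policy, config$montage)
  }
  rec <- hjorth_laplacian(rec, config$montage)
  rereference_average(rec)
}

#' Compute Dual Frequency Head Maps from a preprocessed recording
#'
#' Segmentation, theta/alpha FFT band power, first-minute baseline
#' statistics, z-scoring and DFHM assembly.
#'
#' @param rec a preprocessed \code{eeg_recording}
#' @param config a \code{pipeline_config}
#' @return a \code{dfhm_features}
#' @export
compute_dfhm <- function(rec, config = pipeline_config()) {
  segs <- segment_recording(rec)
  bp <- band_power_multi(segs, list(config$theta, config$alpha))
  bp_th <- bp[[1]]
  bp_al <- bp[[2]]
  st_th <- baseline_stats(bp_th, config$baseline_end)
  st_al <- baseline_stats(bp_al, config$baseline_end)
  build_dfhm(zscore_band_power(bp_th, st_th),
             zscore_band_power(bp_al, st_al),
             config$montage)
}

#' Full chain: raw recording to workload index series
#'
#' @param rec a raw \code{eeg_recording}
#' @param classifier a trained \code{workload_classifier}
#' @param config a \code{pipeline_config}
#' @return a \code{workload_index_series}
#' @export
compute_workload_index <- function(rec, classifier,
                                   config = pipeline_config()) {
  rec <- preprocess_recording(rec, config)
  feats <- compute_dfhm(rec, config)
  workload_index(stats::predict(classifier, feats))
}

#' Run the pipeline over a set of recordings
#'
#' @param recordings named list of raw \code{eeg_recording} objects, or a
#'   character vector of EDF paths
#' @param classifier a trained \code{workload_classifier}
#' @param config a \code{pipeline_config}
#' @param output_dir if non-NULL, one \code{<name>_index.csv} per recording
#'   is written there (each embedding the config hash as a comment line)
#' @param verbose print per-recording progress to stderr?
#' @return object of class \code{pipeline_result}: list with \code{series}
#'   (named list of \code{workload_index_series}) and \code{report}
#'   (parameters, seeds, config hash, package version)
#' @export
run_pipeline <- function(recordings, classifier, config = pipeline_config(),
                         output_dir = NULL, verbose = FALSE) {
  if (is.character(recordings)) {
    paths <- recordings
    recordings <- lapply(paths, load_recording, montage = config$montage)
    names(recordings) <- sub("\\.edf$", "", basename(paths), ignore.case = TRUE)
  }
  if (is.null(names(recordings)) || any(names(recordings) == "")) {
    names(recordings) <- sprintf("recording%03d", seq_along(recordings))
  }
  hash <- config_hash(config)
  series <- list()
  for (nm in names(recordings)) {
    if (verbose) message("processing ", nm)
    series[[nm]] <- compute_workload_index(recordings[[nm]], classifier, config)
    if (!is.null(output_dir)) {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      write_index_csv(series[[nm]],
                      file.path(output_dir, paste0(nm, "_index.csv")),
                      comment = paste0("config_hash=", hash))
    }
  }
  structure(list(series = series,
                 report = list(config_hash = hash,
                               n_recordings = length(series),
                               band = config$band,
                               filter_order = config$filter_order,
                               ica = config$ica, ica_seed = config$ica_seed,
                               theta = config$theta, alpha = config$alpha,
                               baseline_end = config$baseline_end,
                               package_version =
                                 as.character(utils::packageVersion("dfhm")))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$series), " recordings, config ",
      x$report$config_hash, "\n", sep = "")
  invisible(x)
}

#' Synthesize labeled calibration features through the full pipeline
#'
#' Generates calibration scenarios at the four traffic loads for a few
#' synthetic subjects, runs preprocessing and DFHM extraction, and labels
#' the post-baseline segments by the scenario's load level (25 -> low,
#' 35/45 -> moderate, 55 -> high).  This yields training data on exactly
#' the feature scale the pipeline produces at prediction time.
#'
#' @param n_subjects number of calibration subjects, default 2
#' @param duration calibration scenario duration in seconds, default 150
#' @param config a \code{pipeline_config} (ICA off by default here: the
#'   calibration scenarios are generated blink-free)
#' @param seed integer seed
#' @return list with \code{features} (a \code{dfhm_features}) and
#'   \code{labels}
#' @export
synthesize_training_data <- function(n_subjects = 2, duration = 150,
                                     config = pipeline_config(ica = FALSE),
                                     seed = 1) {
  profiles <- cohort_profiles(n_subjects, seed = seed,
                              n_sensitive = ceiling(n_subjects / 2))
  class_of <- c(`25` = 1L, `35` = 2L, `45` = 2L, `55` = 3L)
  feats <- list()
  labels <- list()
  for (p in profiles) {
    for (load in c(25, 35, 45, 55)) {
      d <- scenario_design(load, FALSE, duration = duration,
                           id = load_level(load))
      rec <- generate_eeg(p, d, config$montage)
      f <- compute_dfhm(preprocess_recording(rec, config), config)
      keep <- f$times >= 90          # load effect fully ramped in
      feats[[length(feats) + 1]] <- f$features[keep, , drop = FALSE]
      labels[[length(labels) + 1]] <- rep(class_of[[as.character(load)]],
                                          sum(keep))
    }
  }
  X <- do.call(rbind, feats)
  structure_feats <- structure(list(features = X,
                                    feature_names = colnames(X),
                                    times = 0.5 * (seq_len(nrow(X)) - 1)),
                               class = "dfhm_features")
  list(features = structure_feats, labels = unlist(labels))
}
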