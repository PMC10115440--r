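#' Stimulus and acquisition protocol
#'
#' Describes one recording: sensor modality, AP train, frame rate, and the
#' frame windows used for quantification. Frames are 0-based; frame `i`
#' spans `[i/frame_rate, (i+1)/frame_rate)` seconds.
#'
#' Modality defaults mirror the standard acquisition regimes:
#' \itemize{
#'   \item `physin-gcamp`: 20 AP at 20 Hz, 50 Hz frames, single trial;
#'     peak = mean of the 5 frames ending at train offset.
#'   \item `vgph`: 200 AP at 20 Hz, 5 Hz frames, single trial; peak = mean
#'     of the last 5 frames of the 10 s train; calibration by NH4Cl.
#'   \item `iglusnfr`: 1 AP per trial, 15 trials, 100 Hz frames; peak =
#'     mean of 3 frames with the first coinciding with the AP; calibration
#'     by saturating glutamate.
#' }
#' The recording layout per trial is `baseline | train | post`; after the
#' last trial a `gap` is followed by the calibration epoch (ionomycin,
#' NH4Cl or glutamate depending on modality).
#'
#' @param modality sensor name.
#' @param n_ap APs per trial.
#' @param ap_rate AP rate within the train, Hz.
#' @param frame_rate acquisition rate, Hz.
#' @param baseline_frames pre-stimulus frames used for baseline statistics.
#' @param peak_frames frames averaged for the peak.
#' @param post_frames frames recorded after the train within a trial.
#' @param gap_frames frames between last trial and calibration epoch.
#' @param calib_frames frames of the calibration plateau epoch.
#' @param n_trials number of identical trials (averaged downstream).
#' @return object of class `stimulus_protocol` with derived fields:
#'   `stim_frame`, `train_frames`, `trial_frames`, `peak_window`
#'   (`c(start, length)`, trial-relative), `calibration_window`
#'   (`c(start, length)`, recording-absolute), `total_frames`.
#' @export
stimulus_protocol <- function(modality = c("physin-gcamp", "vgph", "iglusnfr"),
                              n_ap = NULL, ap_rate = 20, frame_rate = NULL,
                              baseline_frames = 49, peak_frames = NULL,
                              post_frames = NULL, gap_frames = NULL,
                              calib_frames = 25, n_trials = NULL) {
  modality <- match.arg(modality)
  def <- switch(modality,
    "physin-gcamp" = list(n_ap = 20, frame_rate = 50, peak_frames = 5,
                          post_frames = 100, gap_frames = 25, n_trials = 1),
    "vgph"         = list(n_ap = 200, frame_rate = 5, peak_frames = 5,
                          post_frames = 50, gap_frames = 10, n_trials = 1),
    "iglusnfr"     = list(n_ap = 1, frame_rate = 100, peak_frames = 3,
                          post_frames = 48, gap_frames = 10, n_trials = 15))
  n_ap        <- if (is.null(n_ap)) def$n_ap else n_ap
  frame_rate  <- if (is.null(frame_rate)) def$frame_rate else frame_rate
  peak_frames <- if (is.null(peak_frames)) def$peak_frames else peak_frames
  post_frames <- if (is.null(post_frames)) def$post_frames else post_frames
  gap_frames  <- if (is.null(gap_frames)) def$gap_frames else gap_frames
  n_trials    <- if (is.null(n_trials)) def$n_trials else n_trials
  stopifnot(n_ap >= 1, ap_rate > 0, frame_rate > 0, baseline_frames >= 2,
            peak_frames >= 1, post_frames >= 0, gap_frames >= 0,
            calib_frames >= 1, n_trials >= 1)

  train_frames <- max(1L, as.integer(round(n_ap / ap_rate * frame_rate)))
  stim_frame <- as.integer(baseline_frames)
  trial_frames <- as.integer(baseline_frames + train_frames + post_frames)
  if (modality == "iglusnfr") {
    # first peak frame coincides with the AP
    peak_window <- c(stim_frame, as.integer(peak_frames))
  } else {
    # peak frames end at train offset
    peak_window <- c(stim_frame + train_frames - as.integer(peak_frames),
                     as.integer(peak_frames))
  }
  if (peak_window[1] < stim_frame)
    stop("stimulus_protocol: peak window precedes the stimulus")
  calib_start <- as.integer(n_trials * trial_frames + gap_frames)
  total_frames <- as.integer(calib_start + calib_frames)
  structure(list(modality = modality, n_ap = as.integer(n_ap),
                 ap_rate = ap_rate, frame_rate = frame_rate,
                 baseline_frames = as.integer(baseline_frames),
                 peak_frames = as.integer(peak_frames),
                 post_frames = as.integer(post_frames),
                 gap_frames = as.integer(gap_frames),
                 calib_frames = as.integer(calib_frames),
                 n_trials = as.integer(n_trials),
                 train_frames = train_frames, stim_frame = stim_frame,
                 trial_frames = trial_frames, peak_window = peak_window,
                 calibration_window = c(calib_start, as.integer(calib_frames)),
                 total_frames = total_frames),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stimulus_protocol %s> %d AP @ %g Hz, %g Hz frames, ",
                     "%d trial(s) x %d frames, %d total frames\n"),
              x$modality, x$n_ap, x$ap_rate, x$frame_rate, x$n_trials,
              x$trial_frames, x$total_frames))
  invisible(x)
}

# user-settable constructor arguments (the rest are derived)
.protocol_user_fields <- c("modality", "n_ap", "ap_rate", "frame_rate",
                           "baseline_frames", "peak_frames", "post_frames",
                           "gap_frames", "calib_frames", "n_trials")

#' Write a protocol to JSON
#' @param protocol a [stimulus_protocol()].
#' @param path output file.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(protocol[.protocol_user_fields], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a protocol from JSON
#' @param path JSON file as written by [write_protocol()].
#' @return a [stimulus_protocol()] with derived fields recomputed.
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .protocol_user_fields)
  if (length(unknown))
    stop("read_protocol: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(stimulus_protocol, raw)
}
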