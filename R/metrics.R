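#' Baseline statistics of a trace
#'
#' Mean and sample SD (denominator N-1) of the configured pre-stimulus
#' frames (default 49, the frames immediately preceding the first stimulus
#' frame of the first trial).
#'
#' @param values numeric trace (trial-aligned; the baseline must be its
#'   first `baseline_frames` frames).
#' @param protocol a [stimulus_protocol()].
#' @return named list `f_baseline`, `sigma_baseline`.
#' @export
baseline_stats <- function(values, protocol) {
  nb <- protocol$baseline_frames
  if (length(values) < nb)
    stop("baseline_stats: trace shorter than baseline window")
  b <- values[seq_len(nb)]
  list(f_baseline = mean(b), sigma_baseline = stats::sd(b))
}

#' Peak fluorescence change above baseline
#'
#' Mean of the modality-specific peak window minus the baseline mean: the
#' 5 frames ending at AP-train offset for the calcium and pHluorin sensors,
#' 3 frames starting at the AP for the glutamate sensor.
#'
#' @param values numeric trace (trial-aligned).
#' @param protocol a [stimulus_protocol()].
#' @param f_baseline baseline mean; computed from `values` if missing.
#' @return `df_peak` in trace units.
#' @export
peak_delta_f <- function(values, protocol, f_baseline = NULL) {
  pw <- protocol$peak_window
  if (pw[1] + pw[2] > length(values))
    stop("peak_delta_f: peak window out of range")
  if (is.null(f_baseline))
    f_baseline <- baseline_stats(values, protocol)$f_baseline
  mean(values[pw[1] + seq_len(pw[2])]) - f_baseline
}

#' Silent/responding classification against baseline noise
#'
#' A terminal is silent iff its peak fluorescence change is strictly less
#' than the baseline SD; equality counts as responding.
#'
#' @param df_peak peak minus baseline, trace units.
#' @param sigma_baseline baseline SD (>= 0), same units.
#' @return logical: `TRUE` when silent (vectorized).
#' @export
classify_silent <- function(df_peak, sigma_baseline) {
  if (any(sigma_baseline < 0))
    stop("classify_silent: sigma_baseline must be >= 0")
  df_peak < sigma_baseline
}

#' Calibration-epoch saturated fluorescence
#'
#' The maximal k-consecutive-frame mean within the calibration window
#' (robust plateau estimate; for a monotone-rising epoch this is the last
#' k frames).
#'
#' @param values numeric full-recording trace (background-corrected).
#' @param protocol a [stimulus_protocol()].
#' @param k plateau length, frames.
#' @return `f_max` in trace units.
#' @export
estimate_fmax <- function(values, protocol, k = 5) {
  cw <- protocol$calibration_window
  if (cw[1] + cw[2] > length(values))
    stop("estimate_fmax: calibration window out of range")
  seg <- values[cw[1] + seq_len(cw[2])]
  k <- min(k, length(seg))
  roll <- stats::filter(seg, rep(1 / k, k), sides = 1)
  max(roll, na.rm = TRUE)
}

#' Absolute calcium influx from fluorescence
#'
#' Converts baseline and peak fluorescence to concentrations via the
#' inverse sensor Hill curve and returns the difference in nM:
#' `1000 * (ca(f_baseline + df_peak) - ca(f_baseline))`. Saturation at the
#' peak propagates as an `NA` influx with `saturated = TRUE`.
#'
#' @param f_baseline baseline fluorescence, a.u.
#' @param df_peak peak minus baseline, a.u.
#' @param f_max saturated fluorescence, a.u.
#' @param sensor a [sensor_model()].
#' @param saturation_guard see [convert_to_calcium()].
#' @return list `delta_ca` (nM), `saturated`, `subfloor` (at baseline).
#' @export
delta_calcium <- function(f_baseline, df_peak, f_max,
                          sensor = sensor_model(),
                          saturation_guard = 0.995) {
  base <- convert_to_calcium(f_baseline, f_max, sensor, saturation_guard)
  peak <- convert_to_calcium(f_baseline + df_peak, f_max, sensor,
                             saturation_guard)
  saturated <- base$saturated | peak$saturated
  delta <- 1000 * (peak$ca - base$ca)
  delta[saturated] <- NA_real_
  list(delta_ca = delta, saturated = saturated, subfloor = base$subfloor)
}

#' Normalize a response to its calibration reference
#'
#' For the pHluorin sensor the reference is the NH4Cl-revealed total pool
#' (`f_max - f_baseline`); for the glutamate sensor it is `f_max` itself.
#'
#' @param df_peak peak minus baseline, a.u.
#' @param reference positive calibration reference, a.u.
#' @return dimensionless `df_peak / reference`.
#' @export
normalize_response <- function(df_peak, reference) {
  if (any(reference <= 0))
    stop("normalize_response: reference must be > 0")
  df_peak / reference
}

#' Quantify every terminal of one recording
#'
#' Runs the full per-terminal measurement chain on a frames-by-terminals
#' trace matrix (background-corrected, or generator traces): trial
#' averaging (glutamate sensor), baseline statistics, peak extraction,
#' silent classification, calibration, and the modality-specific
#' normalization or calcium conversion.
#'
#' @param traces frames-by-terminals numeric matrix with terminal ids as
#'   column names.
#' @param protocol a [stimulus_protocol()].
#' @param sensor a [sensor_model()] (calcium conversion; defaults by
#'   modality).
#' @param neuron_id,condition identifiers copied into the table.
#' @param saturation_guard see [convert_to_calcium()].
#' @return `data.table` with one row per terminal: neuron_id, terminal_id,
#'   condition_mM, modality, f_baseline, sigma_baseline, df_peak, f_max,
#'   silent, response_norm, delta_ca_nM, saturated, subfloor, usable.
#' @export
measure_recording <- function(traces, protocol,
                              sensor = default_sensor(protocol$modality),
                              neuron_id = NA_character_,
                              condition = NA_real_,
                              saturation_guard = 0.995) {
  if (nrow(traces) != protocol$total_frames)
    stop("measure_recording: trace length does not match protocol")
  nt <- ncol(traces)
  ids <- colnames(traces)
  if (is.null(ids)) ids <- sprintf("t%03d", seq_len(nt))
  f_baseline <- sigma_baseline <- df_peak <- f_max <- numeric(nt)
  for (ti in seq_len(nt)) {
    full <- traces[, ti]
    aligned <- if (protocol$n_trials > 1)
      average_trials(split_trials(full, protocol)) $ values else full
    bs <- baseline_stats(aligned, protocol)
    f_baseline[ti] <- bs$f_baseline
    sigma_baseline[ti] <- bs$sigma_baseline
    df_peak[ti] <- peak_delta_f(aligned, protocol, bs$f_baseline)
    f_max[ti] <- estimate_fmax(full, protocol)
  }
  silent <- classify_silent(df_peak, sigma_baseline)
  usable <- f_max > f_baseline
  response_norm <- rep(NA_real_, nt)
  delta_ca <- rep(NA_real_, nt)
  saturated <- subfloor <- rep(FALSE, nt)
  if (protocol$modality == "physin-gcamp") {
    dc <- delta_calcium(f_baseline, df_peak, pmax(f_max, 1e-12), sensor,
                        saturation_guard)
    saturated <- dc$saturated
    subfloor <- dc$subfloor
    delta_ca <- dc$delta_ca
    delta_ca[silent | !usable] <- NA_real_
  } else {
    ref <- if (protocol$modality == "vgph") f_max - f_baseline else f_max
    ok <- usable & ref > 0
    response_norm[ok] <- df_peak[ok] / ref[ok]
    usable <- ok
  }
  data.table::data.table(
    neuron_id = neuron_id, terminal_id = ids, condition_mM = condition,
    modality = protocol$modality, f_baseline = f_baseline,
    sigma_baseline = sigma_baseline, df_peak = df_peak, f_max = f_max,
    silent = silent, response_norm = response_norm, delta_ca_nM = delta_ca,
    saturated = saturated, subfloor = subfloor, usable = usable)
}

#' Quantify every recording of a synthetic dataset (trace path)
#'
#' Convenience wrapper over [measure_recording()] for all neuron-condition
#' recordings of a [generate_dataset()] result, using the noisy traces.
#'
#' @param dataset a `synthetic_dataset`.
#' @param saturation_guard see [convert_to_calcium()].
#' @return combined measurement `data.table`.
#' @export
measure_dataset <- function(dataset, saturation_guard = 0.995) {
  cfg <- dataset$config
  rows <- list()
  for (nid in names(dataset$recordings)) {
    for (key in names(dataset$recordings[[nid]])) {
      rec <- dataset$recordings[[nid]][[key]]
      rows[[paste(nid, key)]] <- measure_recording(
        rec$noisy, cfg$protocol, cfg$sensor, neuron_id = nid,
        condition = as.numeric(key), saturation_guard = saturation_guard)
    }
  }
  data.table::rbindlist(rows)
}
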