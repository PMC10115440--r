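#' Default sensor kinetics per modality
#'
#' Returns a [sensor_model()] with modality-appropriate kinetics:
#' GCaMP6f-like (rise 50 ms, decay 0.5 s), pHluorin pool turnover
#' (rise 2.5 s over the 10 s train, slow 15 s re-acidification), and a fast
#' glutamate transient (rise 2 ms, decay 50 ms).
#'
#' @param modality sensor name.
#' @return a [sensor_model()].
#' @export
default_sensor <- function(modality = c("physin-gcamp", "vgph", "iglusnfr")) {
  modality <- match.arg(modality)
  switch(modality,
    "physin-gcamp" = sensor_model("physin-gcamp", tau_rise = 0.05,
                                  tau_decay = 0.5),
    "vgph" = sensor_model("vgph", tau_rise = 2.5, tau_decay = 15),
    "iglusnfr" = sensor_model("iglusnfr", tau_rise = 0.002,
                              tau_decay = 0.05))
}

#' Ground-truth generator configuration
#'
#' The stated world of the synthetic generator: 9 neurons x 200 terminals
#' per recording, external calcium conditions spanning the physiologic set
#' point, linear influx with x-intercept 0.47 mM, probabilistic all-or-none
#' silencing following the population Hill curve (Kd 25 nM, coefficient
#' 1.79), resting calcium 0.05 µM, and EMCCD-like counts (read noise plus a
#' signal-scaled Gaussian shot term, 16-bit with 100-count camera offset).
#'
#' @param n_neurons neurons (independent recordings per condition).
#' @param n_terminals_per_neuron terminals per recording.
#' @param ca_e_conditions external calcium conditions, mM.
#' @param protocol a [stimulus_protocol()]; default chosen by `modality`.
#' @param modality sensor modality (used when `protocol`/`sensor` are NULL).
#' @param sensor a [sensor_model()].
#' @param influx an [influx_model()].
#' @param silencing a [silencing_model()].
#' @param resting_ca resting intracellular calcium, µM.
#' @param f_max_mean mean saturated fluorescence per terminal, counts.
#' @param f_max_cv coefficient of variation of `f_max` across terminals.
#' @param baseline_frac resting fractional fluorescence for non-calcium
#'   sensors (vGpH surface fraction / iGluSnFR resting signal).
#' @param resp_frac_ref response fraction (of pool for vGpH, of F_max for
#'   iGluSnFR) of a responding terminal at 2.0 mM external calcium.
#' @param noise list with `read_sd` (additive Gaussian SD, counts) and
#'   `shot_scale` (variance per count of signal, Gaussian shot
#'   approximation).
#' @param perturbation fractional influx reduction in `[0, 1)` applied
#'   before silencing draws (GPCR agonism / partial channel block
#'   emulation; ~0.4 mimics baclofen).
#' @param traces_only skip movie rendering and emit traces directly.
#' @param geometry list of movie-rendering parameters: `width`, `height`
#'   (pixels), `psf_sigma` (px), `min_separation` (px), `background`
#'   (diffuse axon level, counts), `offset` (camera offset, counts).
#' @param seed integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_neurons = 9, n_terminals_per_neuron = 200,
                             ca_e_conditions = c(2.0, 1.2, 0.8, 0.4),
                             protocol = NULL,
                             modality = "physin-gcamp",
                             sensor = NULL,
                             influx = influx_model(),
                             silencing = silencing_model(),
                             resting_ca = 0.05,
                             f_max_mean = 2000, f_max_cv = 0.2,
                             baseline_frac = 0.06, resp_frac_ref = 0.30,
                             noise = list(read_sd = 2, shot_scale = 0.01),
                             perturbation = 0,
                             traces_only = TRUE,
                             geometry = list(width = 160, height = 160,
                                             psf_sigma = 1.5,
                                             min_separation = 4,
                                             background = 20, offset = 100),
                             seed = 1L) {
  if (is.null(protocol)) protocol <- stimulus_protocol(modality)
  if (is.null(sensor)) sensor <- default_sensor(protocol$modality)
  cfg <- structure(list(n_neurons = as.integer(n_neurons),
                        n_terminals_per_neuron =
                          as.integer(n_terminals_per_neuron),
                        ca_e_conditions = as.numeric(ca_e_conditions),
                        protocol = protocol, sensor = sensor,
                        influx = influx, silencing = silencing,
                        resting_ca = resting_ca,
                        f_max_mean = f_max_mean, f_max_cv = f_max_cv,
                        baseline_frac = baseline_frac,
                        resp_frac_ref = resp_frac_ref,
                        noise = noise, perturbation = perturbation,
                        traces_only = isTRUE(traces_only),
                        geometry = geometry, seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Collects every violated invariant and fails listing all of them.
#' @param cfg a `generator_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_generator_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$n_neurons >= 1, "n_neurons must be >= 1")
  chk(cfg$n_terminals_per_neuron >= 1,
      "n_terminals_per_neuron must be >= 1")
  chk(length(cfg$ca_e_conditions) >= 1 && all(cfg$ca_e_conditions > 0),
      "ca_e_conditions must be non-empty and positive")
  chk(inherits(cfg$protocol, "stimulus_protocol"),
      "protocol must be a stimulus_protocol")
  chk(inherits(cfg$sensor, "sensor_model"), "sensor must be a sensor_model")
  chk(inherits(cfg$influx, "influx_model"), "influx must be an influx_model")
  chk(inherits(cfg$silencing, "silencing_model"),
      "silencing must be a silencing_model")
  chk(cfg$resting_ca > 0, "resting_ca must be > 0")
  chk(cfg$f_max_mean > 0, "f_max_mean must be > 0")
  chk(cfg$f_max_cv >= 0, "f_max_cv must be >= 0")
  chk(cfg$baseline_frac > 0 && cfg$baseline_frac < 1,
      "baseline_frac must be in (0, 1)")
  chk(cfg$resp_frac_ref > 0 && cfg$resp_frac_ref <= 1,
      "resp_frac_ref must be in (0, 1]")
  chk(is.numeric(cfg$noise$read_sd) && cfg$noise$read_sd >= 0,
      "noise$read_sd must be >= 0")
  chk(is.numeric(cfg$noise$shot_scale) && cfg$noise$shot_scale >= 0,
      "noise$shot_scale must be >= 0")
  chk(cfg$perturbation >= 0 && cfg$perturbation < 1,
      "perturbation must be in [0, 1)")
  geo <- cfg$geometry
  chk(all(c("width", "height", "psf_sigma", "min_separation", "background",
            "offset") %in% names(geo)), "geometry is missing fields")
  if (length(bad))
    stop("invalid generator config:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(cfg)
}

# Deterministic per-stream child seed below 2^31, prefix-stable in `index`.
child_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 2654435761 + index * 40503 + stream * 69069 +
     12345) %% 2147483647
}

# Normalized activation time course of one trial (frames at centre times).
# First-order saturating approach to the train plateau, exponential decay
# after train offset. Returns values in [0, 1], length = trial_frames.
trial_activation <- function(protocol, sensor) {
  t <- (seq_len(protocol$trial_frames) - 0.5) / protocol$frame_rate
  t_on <- protocol$stim_frame / protocol$frame_rate
  train_dur <- protocol$n_ap / protocol$ap_rate
  g <- numeric(protocol$trial_frames)
  rising <- t >= t_on & t < t_on + train_dur
  g[rising] <- 1 - exp(-(t[rising] - t_on) / sensor$tau_rise)
  g_end <- 1 - exp(-train_dur / sensor$tau_rise)
  post <- t >= t_on + train_dur
  g[post] <- g_end * exp(-(t[post] - t_on - train_dur) / sensor$tau_decay)
  g
}

#' Simulate a single terminal's fluorescence trace
#'
#' Forward model of one recording for one terminal at one condition:
#' baseline at the resting-state fluorescence, a stimulus-locked transient
#' rising toward the evoked level with `tau_rise` and decaying with
#' `tau_decay` (absent when the terminal is silent), repeated over trials,
#' and a calibration plateau at `F = f_max` (ionomycin / NH4Cl / saturating
#' glutamate depending on modality). Noise is additive Gaussian read noise
#' plus a Gaussian shot-like term with variance proportional to the signal;
#' noise is drawn from the current RNG state.
#'
#' @param terminal list with `f_max`, `resting_ca`, and per-condition
#'   `delta_ca_true` (nM) and `silent_true` (named by condition label, as
#'   produced by [generate_dataset()]); for non-calcium sensors also
#'   `baseline_frac` and per-condition `resp_frac`.
#' @param condition external calcium, mM (must be a keyed condition).
#' @param protocol a [stimulus_protocol()].
#' @param sensor a [sensor_model()].
#' @param noise list with `read_sd`, `shot_scale`.
#' @return list with `noiseless` and `noisy` numeric vectors of length
#'   `protocol$total_frames`.
#' @export
simulate_terminal_trace <- function(terminal, condition, protocol,
                                    sensor = default_sensor(protocol$modality),
                                    noise = list(read_sd = 0,
                                                 shot_scale = 0)) {
  key <- condition_key(condition)
  if (!key %in% names(terminal$delta_ca_true))
    stop("simulate_terminal_trace: unknown condition ", key)
  silent <- isTRUE(terminal$silent_true[[key]])
  g <- trial_activation(protocol, sensor)
  n <- protocol$total_frames
  trace <- numeric(n)
  if (protocol$modality == "physin-gcamp") {
    delta_uM <- if (silent) 0 else terminal$delta_ca_true[[key]] / 1000
    ca <- terminal$resting_ca + delta_uM * g
    block <- terminal$f_max * sensor_forward(ca, sensor)
    base_val <- terminal$f_max * sensor_forward(terminal$resting_ca, sensor)
  } else {
    f_base <- terminal$baseline_frac * terminal$f_max
    resp <- if (silent) 0 else terminal$resp_frac[[key]]
    amp <- if (protocol$modality == "vgph")
      resp * (terminal$f_max - f_base) else resp * terminal$f_max
    block <- f_base + amp * g
    base_val <- f_base
  }
  for (tr in seq_len(protocol$n_trials)) {
    i0 <- (tr - 1L) * protocol$trial_frames
    trace[i0 + seq_len(protocol$trial_frames)] <- block
  }
  gap_idx <- seq(protocol$n_trials * protocol$trial_frames + 1L,
                 length.out = protocol$gap_frames)
  if (protocol$gap_frames > 0) trace[gap_idx] <- base_val
  calib_idx <- protocol$calibration_window[1] + seq_len(protocol$calib_frames)
  trace[calib_idx] <- terminal$f_max
  noisy <- trace +
    stats::rnorm(n, 0, sqrt(noise$read_sd^2 +
                              noise$shot_scale * pmax(trace, 0)))
  list(noiseless = trace, noisy = noisy)
}

condition_key <- function(ca_e) sprintf("%g", ca_e)

# Sample terminal positions along axon-like polyline paths with minimum
# pairwise separation and an in-bounds margin. Falls back to uniform
# rejection sampling for stragglers; errors if the field cannot fit them.
sample_positions <- function(n, geometry) {
  w <- geometry$width; h <- geometry$height
  sep <- geometry$min_separation
  margin <- max(4, ceiling(3 * geometry$psf_sigma))
  pts <- matrix(numeric(0), ncol = 2)
  ok_sep <- function(p) {
    nrow(pts) == 0 || min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= sep^2
  }
  n_axons <- max(1L, ceiling(n / 25))
  for (a in seq_len(n_axons)) {
    x <- stats::runif(1, margin, w - margin)
    y <- stats::runif(1, margin, h - margin)
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(60)) {
      if (nrow(pts) >= n) break
      step <- stats::runif(1, sep, 2 * sep)
      ang <- ang + stats::rnorm(1, 0, 0.35)
      x <- min(max(x + step * cos(ang), margin), w - margin)
      y <- min(max(y + step * sin(ang), margin), h - margin)
      p <- c(x + stats::rnorm(1, 0, 0.5), y + stats::rnorm(1, 0, 0.5))
      p <- pmin(pmax(p, margin), c(w, h) - margin)
      if (ok_sep(p)) pts <- rbind(pts, p)
    }
    if (nrow(pts) >= n) break
  }
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    p <- c(stats::runif(1, margin, w - margin),
           stats::runif(1, margin, h - margin))
    if (ok_sep(p)) pts <- rbind(pts, p)
    tries <- tries + 1
  }
  if (nrow(pts) < n)
    stop("sample_positions: cannot place ", n, " terminals at separation ",
         sep, " in a ", w, "x", h, " field")
  pts <- pts[seq_len(n), , drop = FALSE]
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Generate a ground-truth synthetic dataset
#'
#' Draws per-terminal ground truth (saturated fluorescence, influx per
#' condition, all-or-none silent state) and simulates every recording.
#' Silencing uses one uniform draw `u` per terminal reused at every
#' condition (silent when `u < p(influx)`), so a terminal silent at some
#' external calcium stays silent at every lower influx — the within-terminal
#' monotone coupling the all-or-none phenotype implies. In hard-threshold
#' mode a terminal is silent iff its influx is below `kd_sil`. A
#' `perturbation` multiplies influx by `1 - perturbation` before the
#' silencing draw.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_dataset`: list with `config`,
#'   `ground_truth` (a `data.table`: neuron_id, terminal_id, x, y, f_max,
#'   condition_mM, delta_ca_true_nM, silent_true, response_norm_true),
#'   `recordings` (nested list `[[neuron_id]][[condition key]]` with
#'   `noisy` / `noiseless` frame-by-terminal matrices, `positions`,
#'   `terminal_ids`, and — unless `traces_only` — a rendered `movie`),
#'   and `manifest` (all parameters plus the seed).
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  protocol <- config$protocol
  conditions <- config$ca_e_conditions
  keys <- vapply(conditions, condition_key, "")
  influx_ref <- influx_at(2.0, config$influx)

  gt_rows <- vector("list", config$n_neurons)
  recordings <- vector("list", config$n_neurons)
  neuron_ids <- sprintf("neuron%02d", seq_len(config$n_neurons))
  names(recordings) <- neuron_ids

  for (ni in seq_len(config$n_neurons)) {
    set.seed(child_seed(config$seed, ni, stream = 1L))
    nt <- config$n_terminals_per_neuron
    f_max <- config$f_max_mean *
      exp(stats::rnorm(nt, 0, config$f_max_cv)) /
      exp(config$f_max_cv^2 / 2)
    u <- stats::runif(nt)
    positions <- sample_positions(nt, config$geometry)
    term_ids <- sprintf("%s_t%03d", neuron_ids[ni], seq_len(nt))

    # per-condition ground truth
    delta_mat <- matrix(0, nt, length(conditions),
                        dimnames = list(NULL, keys))
    silent_mat <- matrix(FALSE, nt, length(conditions),
                         dimnames = list(NULL, keys))
    resp_mat <- matrix(0, nt, length(conditions),
                       dimnames = list(NULL, keys))
    for (ci in seq_along(conditions)) {
      delta <- influx_at(conditions[ci], config$influx) *
        (1 - config$perturbation)
      p_sil <- silencing_probability(delta, config$silencing)
      silent <- if (config$silencing$mode == "probabilistic")
        u < p_sil else rep(delta < config$silencing$kd_sil, nt)
      delta_mat[, ci] <- delta
      silent_mat[, ci] <- silent
      resp_mat[, ci] <- config$resp_frac_ref * delta / influx_ref
    }

    cond_recs <- vector("list", length(conditions))
    names(cond_recs) <- keys
    for (ci in seq_along(conditions)) {
      set.seed(child_seed(config$seed, ni, stream = 100L + ci))
      noiseless <- matrix(0, protocol$total_frames, nt)
      noisy <- matrix(0, protocol$total_frames, nt)
      for (ti in seq_len(nt)) {
        term <- list(f_max = f_max[ti], resting_ca = config$resting_ca,
                     baseline_frac = config$baseline_frac,
                     delta_ca_true = as.list(delta_mat[ti, ]),
                     silent_true = as.list(silent_mat[ti, ]),
                     resp_frac = as.list(resp_mat[ti, ]))
        tr <- simulate_terminal_trace(term, conditions[ci], protocol,
                                      config$sensor, config$noise)
        noiseless[, ti] <- tr$noiseless
        noisy[, ti] <- tr$noisy
      }
      colnames(noiseless) <- term_ids
      colnames(noisy) <- term_ids
      rec <- list(noisy = noisy, noiseless = noiseless,
                  positions = positions, terminal_ids = term_ids)
      if (!config$traces_only) {
        set.seed(child_seed(config$seed, ni, stream = 200L + ci))
        rec$movie <- render_movie(positions, noisy, config$geometry,
                                  noise = config$noise)
      }
      cond_recs[[ci]] <- rec
    }
    recordings[[ni]] <- cond_recs

    gt_rows[[ni]] <- data.table::data.table(
      neuron_id = neuron_ids[ni],
      terminal_id = rep(term_ids, times = length(conditions)),
      x = rep(positions[, "x"], times = length(conditions)),
      y = rep(positions[, "y"], times = length(conditions)),
      f_max = rep(f_max, times = length(conditions)),
      condition_mM = rep(conditions, each = nt),
      delta_ca_true_nM = as.vector(delta_mat),
      silent_true = as.vector(silent_mat),
      response_norm_true = as.vector(resp_mat))
  }

  manifest <- c(list(tool = "boutonsilence",
                     version = as.character(utils::packageVersion("boutonsilence"))),
                manifest_fields(config))
  structure(list(config = config,
                 ground_truth = data.table::rbindlist(gt_rows),
                 recordings = recordings, manifest = manifest),
            class = "synthetic_dataset")
}

manifest_fields <- function(config) {
  list(seed = config$seed, n_neurons = config$n_neurons,
       n_terminals_per_neuron = config$n_terminals_per_neuron,
       ca_e_conditions = config$ca_e_conditions,
       modality = config$protocol$modality,
       protocol = config$protocol[.protocol_user_fields],
       sensor = unclass(config$sensor),
       influx = unclass(config$influx),
       silencing = unclass(config$silencing),
       resting_ca = config$resting_ca, f_max_mean = config$f_max_mean,
       f_max_cv = config$f_max_cv, baseline_frac = config$baseline_frac,
       resp_frac_ref = config$resp_frac_ref, noise = config$noise,
       perturbation = config$perturbation,
       traces_only = config$traces_only, geometry = config$geometry)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d neurons x %d terminals x %d ",
                     "conditions (%s), %s\n"),
              x$config$n_neurons, x$config$n_terminals_per_neuron,
              length(x$config$ca_e_conditions), x$config$protocol$modality,
              if (x$config$traces_only) "traces only" else "with movies"))
  invisible(x)
}
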