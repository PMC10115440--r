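#' Hill-type fluorescent sensor model
#'
#' Parameterizes the equilibrium fluorescence-to-ligand mapping of a
#' genetically encoded sensor. For the calcium sensors the mapping is the
#' standard Hill binding curve with dynamic range \eqn{R_f = F_{max}/F_{min}}:
#' \deqn{F/F_{max} = 1/R_f + (1 - 1/R_f)\, \frac{C^n}{C^n + K_d^n}}
#' GCaMP6f defaults are the in vitro constants \eqn{K_d = 0.38} µM,
#' \eqn{R_f = 51.8}, \eqn{n = 2.3}.
#'
#' @param name sensor modality, one of `"physin-gcamp"`, `"vgph"`,
#'   `"iglusnfr"`.
#' @param kd_sensor dissociation constant in µM (calcium sensors only).
#' @param rf dynamic range (dimensionless, > 1).
#' @param hill_n Hill coefficient of the binding curve.
#' @param tau_rise response rise time constant, s.
#' @param tau_decay response decay time constant, s.
#' @return object of class `sensor_model`.
#' @export
sensor_model <- function(name = c("physin-gcamp", "vgph", "iglusnfr"),
                         kd_sensor = 0.38, rf = 51.8, hill_n = 2.3,
                         tau_rise = 0.05, tau_decay = 0.5) {
  name <- match.arg(name)
  stopifnot(rf > 1, kd_sensor > 0, hill_n > 0, tau_rise < tau_decay,
            tau_rise > 0)
  structure(list(name = name, kd_sensor = kd_sensor, rf = rf,
                 hill_n = hill_n, tau_rise = tau_rise,
                 tau_decay = tau_decay),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model %s> Kd=%g uM, Rf=%g, n=%g, tau=%g/%g s\n",
              x$name, x$kd_sensor, x$rf, x$hill_n, x$tau_rise, x$tau_decay))
  invisible(x)
}

#' Forward sensor model: calcium to fractional fluorescence
#'
#' Maps free calcium concentration to equilibrium fractional fluorescence
#' \eqn{F/F_{max}}. At zero calcium returns \eqn{1/R_f}; saturates at 1.
#' The exact algebraic inverse is [convert_to_calcium()].
#'
#' @param ca calcium concentration, µM (vectorized, >= 0).
#' @param sensor a [sensor_model()].
#' @return fractional fluorescence in `[1/Rf, 1]`.
#' @export
sensor_forward <- function(ca, sensor = sensor_model()) {
  if (any(ca < 0)) stop("sensor_forward: ca must be >= 0")
  cn <- ca^sensor$hill_n
  kn <- sensor$kd_sensor^sensor$hill_n
  1 / sensor$rf + (1 - 1 / sensor$rf) * cn / (cn + kn)
}

#' Convert fluorescence to absolute calcium concentration
#'
#' Inverts the sensor Hill curve:
#' \deqn{[Ca^{2+}]_i = K_d \left(\frac{F/F_{max} - 1/R_f}{1 - F/F_{max}}\right)^{1/n}}
#' Fluorescence at or below the zero-calcium floor \eqn{1/R_f} (possible
#' under noise) maps to 0 µM with `subfloor = TRUE`. Fractional fluorescence
#' at or above `saturation_guard` is flagged `saturated` and yields `NA`
#' (the inversion diverges as \eqn{F/F_{max} \to 1}).
#'
#' @param f fluorescence, arbitrary units (vectorized).
#' @param f_max saturated fluorescence of the same terminal, same units (> 0).
#' @param sensor a [sensor_model()].
#' @param saturation_guard upper fractional-fluorescence bound for a usable
#'   inversion; set to 1 (or higher) to disable.
#' @return list with `ca` (µM, `NA` where saturated), logical vectors
#'   `subfloor` and `saturated`.
#' @export
convert_to_calcium <- function(f, f_max, sensor = sensor_model(),
                               saturation_guard = 0.995) {
  if (any(f_max <= 0)) stop("convert_to_calcium: f_max must be > 0")
  frac <- f / f_max
  subfloor <- frac <= 1 / sensor$rf
  saturated <- frac >= saturation_guard
  ratio <- (frac - 1 / sensor$rf) / (1 - frac)
  ca <- sensor$kd_sensor * pmax(ratio, 0)^(1 / sensor$hill_n)
  ca[subfloor] <- 0
  ca[saturated] <- NA_real_
  list(ca = ca, subfloor = subfloor, saturated = saturated)
}
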