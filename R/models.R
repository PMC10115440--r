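#' Linear influx model for external-calcium dependence
#'
#' Empirical linear model of single-AP-train calcium influx versus external
#' calcium, with an x-intercept below which influx collapses to a small
#' residual. Defaults: intercept 0.47 mM (the concentration at which entry
#' ceases by linear extrapolation), slope 39.2 nM/mM (about 60 nM influx at
#' 2.0 mM), residual 5.9 nM — the per-responder influx at which the default
#' silencing Hill curve reproduces the observed ~93% silencing below the
#' intercept (the resulting population-mean influx, ~0.4 nM across all
#' terminals, matches the near-zero residual entry measured at 0.4 mM).
#'
#' @param intercept_ca_e external calcium at which influx vanishes, mM.
#' @param slope influx gain, nM per mM.
#' @param residual sub-intercept residual influx of a non-silenced
#'   terminal, nM (small relative to `slope`).
#' @return object of class `influx_model`.
#' @export
influx_model <- function(intercept_ca_e = 0.47, slope = 39.2,
                         residual = 5.9) {
  stopifnot(intercept_ca_e >= 0, slope > 0, residual >= 0,
            residual < slope * 0.25)
  structure(list(intercept_ca_e = intercept_ca_e, slope = slope,
                 residual = residual),
            class = "influx_model")
}

#' Calcium influx at a given external calcium concentration
#'
#' Piecewise-linear hinge: `max(slope * (ca_e - intercept), residual)`.
#' Continuous and non-decreasing in `ca_e`.
#'
#' @param ca_e external calcium, mM (vectorized, > 0).
#' @param model an [influx_model()].
#' @return influx, nM.
#' @export
influx_at <- function(ca_e, model = influx_model()) {
  if (any(ca_e <= 0)) stop("influx_at: ca_e must be > 0")
  pmax(model$slope * (ca_e - model$intercept_ca_e), model$residual)
}

#' Silencing model: probability of terminal silence versus influx
#'
#' Decreasing Hill curve pinned to probability 1 at zero influx:
#' \deqn{p(\Delta) = K_d^c / (K_d^c + \Delta^c)}
#' Defaults are the fitted population curve (Kd 25 nM, coefficient 1.79;
#' the reporting convention writes the exponent as -1.79 for the decreasing
#' branch, the stored `coeff` is its magnitude). `mode` selects whether a
#' terminal's silent state is drawn probabilistically or thresholded hard
#' at `kd_sil`.
#'
#' @param kd_sil influx at half-maximal silencing, nM.
#' @param coeff positive steepness exponent.
#' @param mode `"probabilistic"` or `"hard-threshold"`.
#' @return object of class `silencing_model`.
#' @export
silencing_model <- function(kd_sil = 25, coeff = 1.79,
                            mode = c("probabilistic", "hard-threshold")) {
  mode <- match.arg(mode)
  stopifnot(kd_sil > 0, coeff > 0)
  structure(list(kd_sil = kd_sil, coeff = coeff, mode = mode),
            class = "silencing_model")
}

#' Probability that a terminal is silent given its calcium influx
#'
#' @param delta_ca influx, nM (vectorized, >= 0).
#' @param model a [silencing_model()].
#' @return probability in (0, 1]; exactly 1 at zero influx.
#' @export
silencing_probability <- function(delta_ca, model = silencing_model()) {
  if (any(delta_ca < 0)) stop("silencing_probability: delta_ca must be >= 0")
  kc <- model$kd_sil^model$coeff
  kc / (kc + delta_ca^model$coeff)
}
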