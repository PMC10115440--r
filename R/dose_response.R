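#' Expected influx under strict proportionality to external calcium
#'
#' The null model against which sub-proportionality is judged: influx at a
#' target concentration scaled from a reference condition by the ratio of
#' external calcium concentrations.
#'
#' @param delta_ref influx at the reference condition, nM.
#' @param ca_ref reference external calcium, mM (> 0).
#' @param ca_target target external calcium, mM.
#' @return expected influx, nM.
#' @export
expected_proportional_delta <- function(delta_ref, ca_ref, ca_target) {
  if (any(ca_ref <= 0))
    stop("expected_proportional_delta: ca_ref must be > 0")
  delta_ref * (ca_target / ca_ref)
}

#' Ordinary least-squares line with x-intercept extrapolation
#'
#' Fits `delta_ca ~ ca_e` by OLS over the supplied points (typically one
#' per-neuron mean per condition) and extrapolates the external calcium at
#' which influx ceases: `intercept_x = -b/m`.
#'
#' @param ca_e abscissae, mM (>= 2 distinct values).
#' @param delta_ca ordinates, nM.
#' @return list of class `linear_fit`: `slope` (nM/mM), `intercept` (nM),
#'   `intercept_x` (mM), `r2`, `n`, `warn_nonpositive_slope`.
#' @export
fit_linear_intercept <- function(ca_e, delta_ca) {
  stopifnot(length(ca_e) == length(delta_ca))
  if (length(unique(ca_e)) < 2)
    stop("fit_linear_intercept: need >= 2 distinct ca_e values")
  m <- stats::cov(ca_e, delta_ca) / stats::var(ca_e)
  b <- mean(delta_ca) - m * mean(ca_e)
  fitted <- m * ca_e + b
  ss_res <- sum((delta_ca - fitted)^2)
  ss_tot <- sum((delta_ca - mean(delta_ca))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  warn <- m <= 0
  if (warn) warning("fit_linear_intercept: non-positive slope; ",
                    "x-intercept extrapolation is unreliable")
  structure(list(slope = m, intercept = b, intercept_x = -b / m, r2 = r2,
                 n = length(ca_e), warn_nonpositive_slope = warn),
            class = "linear_fit")
}

#' Silencing change per unit external calcium
#'
#' `(frac_low - frac_high) / (ca_high - ca_low)`: positive when silencing
#' increases as external calcium falls.
#'
#' @param frac_low silent percentage at the lower concentration.
#' @param frac_high silent percentage at the higher concentration.
#' @param ca_low,ca_high the two external calcium concentrations, mM
#'   (`ca_low < ca_high`).
#' @return slope, percent per mM.
#' @export
silencing_slope <- function(frac_low, frac_high, ca_low, ca_high) {
  if (any(ca_low >= ca_high))
    stop("silencing_slope: requires ca_low < ca_high")
  (frac_low - frac_high) / (ca_high - ca_low)
}

#' Constrained Hill fit of silent fraction versus calcium influx
#'
#' Least-squares fit of the decreasing Hill curve
#' \deqn{S(\Delta) = 100 \cdot K_d^c / (K_d^c + \Delta^c)}
#' with the maximum pinned to 100% at zero influx. Optimized over
#' `(log Kd, log c)` from a deterministic multi-start grid
#' (Kd in {5, 15, 45, 135} nM x c in {0.5, 1, 2, 4}); best final SSE wins,
#' ties broken by smallest Kd. The reporting convention for the decreasing
#' branch writes the exponent as `-c` (`coeff_report`).
#'
#' @param delta_ca influx abscissae, nM (>= 3 points, positive spread).
#' @param silent_pct silent percentages (0-100).
#' @param weights optional non-negative weights (e.g. `1/SEM^2`).
#' @return list of class `hill_fit`: `kd` (nM), `coeff`, `coeff_report`
#'   (`-coeff`), `r2`, `sse`, `n`, `converged`.
#' @export
fit_hill_silencing <- function(delta_ca, silent_pct, weights = NULL) {
  stopifnot(length(delta_ca) == length(silent_pct))
  keep <- is.finite(delta_ca) & is.finite(silent_pct)
  delta_ca <- delta_ca[keep]; silent_pct <- silent_pct[keep]
  if (length(delta_ca) < 3)
    stop("fit_hill_silencing: need >= 3 finite points")
  pos <- delta_ca[delta_ca > 0]
  if (length(unique(pos)) < 2)
    stop("fit_hill_silencing: insufficient spread in positive delta_ca")
  w <- if (is.null(weights)) rep(1, length(delta_ca)) else weights[keep]
  stopifnot(all(w >= 0), length(w) == length(delta_ca))
  model <- function(par) {
    kd <- exp(par[1]); cc <- exp(par[2])
    kc <- kd^cc
    100 * kc / (kc + delta_ca^cc)
  }
  sse <- function(par) {
    r <- silent_pct - model(par)
    s <- sum(w * r * r)
    if (!is.finite(s)) 1e18 else s
  }
  starts <- expand.grid(kd = c(5, 15, 45, 135), cc = c(0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(log(c(starts$kd[i], starts$cc[i])), sse,
                    control = list(rel.tol = 1e-14, eval.max = 2000,
                                   iter.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-12 ||
        (abs(fit$objective - best$objective) <= 1e-12 &&
         exp(fit$par[1]) < exp(best$par[1])))
      best <- fit
  }
  if (is.null(best))
    stop("fit_hill_silencing: no start converged (", length(delta_ca),
         " points, delta range [", min(delta_ca), ", ", max(delta_ca), "])")
  fitted <- model(best$par)
  ss_res <- sum(w * (silent_pct - fitted)^2)
  mw <- sum(w * silent_pct) / sum(w)
  ss_tot <- sum(w * (silent_pct - mw)^2)
  structure(list(kd = exp(best$par[1]), coeff = exp(best$par[2]),
                 coeff_report = -exp(best$par[2]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 sse = best$objective, n = length(delta_ca),
                 converged = best$convergence == 0),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Kd = %.3g nM, n = %.3g (reported %.3g), r2 = %.4f\n",
              x$kd, x$coeff, x$coeff_report, x$r2))
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4g nM/mM, x-intercept = %.4g mM, r2 = %.4f\n",
              x$slope, x$intercept_x, x$r2))
  invisible(x)
}

#' Per-neuron, per-condition summaries and across-neuron statistics
#'
#' Reduces a terminal measurement table to silent fractions and responder
#' means per neuron and condition, then aggregates across neurons: mean,
#' SEM (SD/sqrt(n), sample SD) and CoV (SD/mean of the silent fractions).
#' Responder means cover non-silent, non-saturated, non-subfloor usable
#' terminals. Neurons with no usable terminal in a condition are excluded
#' (reported in `excluded`).
#'
#' @param measurements a table from [measure_recording()].
#' @return list with `per_neuron` (`data.table`: neuron_id, condition_mM,
#'   n_terminals, n_usable, silent_fraction, responder_mean_delta_ca,
#'   responder_mean_response_norm, n_responders), `per_condition`
#'   (`data.table`: condition_mM, n_neurons, mean/sem/cov of silent
#'   fraction, mean responder influx/response), `excluded`.
#' @export
summarize_condition <- function(measurements) {
  dt <- data.table::as.data.table(measurements)
  if (nrow(dt) == 0) stop("summarize_condition: empty measurement table")
  usable <- dt[usable == TRUE]
  excluded <- data.table::fsetdiff(unique(dt[, c("neuron_id", "condition_mM")]),
                                   unique(usable[, c("neuron_id", "condition_mM")]))
  per_neuron <- usable[, {
    resp <- !silent & !saturated & !subfloor
    list(n_terminals = .N,
         n_usable = .N,
         silent_fraction = mean(silent),
         responder_mean_delta_ca = if (any(resp & is.finite(delta_ca_nM)))
           mean(delta_ca_nM[resp], na.rm = TRUE) else NA_real_,
         responder_mean_response_norm = if (any(resp & is.finite(response_norm)))
           mean(response_norm[resp], na.rm = TRUE) else NA_real_,
         n_responders = sum(resp))
  }, by = c("neuron_id", "condition_mM")]
  data.table::setorder(per_neuron, condition_mM, neuron_id)
  per_condition <- per_neuron[, {
    sf <- silent_fraction
    list(n_neurons = .N,
         silent_fraction_mean = mean(sf),
         silent_fraction_sem = if (.N > 1) stats::sd(sf) / sqrt(.N) else NA_real_,
         silent_fraction_cov = if (mean(sf) > 0 && .N > 1)
           stats::sd(sf) / mean(sf) else NA_real_,
         responder_mean_delta_ca = mean(responder_mean_delta_ca, na.rm = TRUE),
         responder_mean_response_norm =
           mean(responder_mean_response_norm, na.rm = TRUE))
  }, by = "condition_mM"]
  data.table::setorder(per_condition, -condition_mM)
  list(per_neuron = per_neuron, per_condition = per_condition,
       excluded = excluded)
}

#' Empirical CDFs of peak fluorescence change by response class
#'
#' @param measurements a table from [measure_recording()].
#' @return `data.table`: condition_mM, class (`silent`/`responding`),
#'   value (sorted df_peak), ecdf (step height at the value).
#' @export
ecdf_by_class <- function(measurements) {
  dt <- data.table::as.data.table(measurements)[usable == TRUE]
  out <- dt[, {
    v <- sort(df_peak)
    list(value = v, ecdf = seq_along(v) / length(v))
  }, by = list(condition_mM,
               class = ifelse(silent, "silent", "responding"))]
  out
}

#' Paired per-neuron effect of a perturbation
#'
#' Matches per-neuron summaries by neuron id (and condition when present)
#' and returns post-minus-pre differences with across-neuron mean and SEM.
#' No hypothesis test is performed.
#'
#' @param pre,post `per_neuron` tables from [summarize_condition()].
#' @return list with `per_neuron` (deltas) and `overall` (mean, sem per
#'   condition).
#' @export
paired_effect <- function(pre, post) {
  pre <- data.table::as.data.table(pre)
  post <- data.table::as.data.table(post)
  keys <- intersect(c("neuron_id", "condition_mM"), names(pre))
  missing_post <- data.table::fsetdiff(pre[, ..keys], post[, ..keys])
  missing_pre <- data.table::fsetdiff(post[, ..keys], pre[, ..keys])
  if (nrow(missing_post) || nrow(missing_pre)) {
    bad <- unique(c(missing_post$neuron_id, missing_pre$neuron_id))
    stop("paired_effect: unmatched neuron ids: ",
         paste(bad, collapse = ", "))
  }
  merged <- merge(pre, post, by = keys, suffixes = c("_pre", "_post"))
  merged[, `:=`(
    d_silent_fraction = silent_fraction_post - silent_fraction_pre,
    d_responder_mean_delta_ca =
      responder_mean_delta_ca_post - responder_mean_delta_ca_pre,
    d_responder_mean_response_norm =
      responder_mean_response_norm_post - responder_mean_response_norm_pre)]
  by_cond <- if ("condition_mM" %in% keys) "condition_mM" else character(0)
  overall <- merged[, list(
    n_neurons = .N,
    d_silent_fraction_mean = mean(d_silent_fraction),
    d_silent_fraction_sem = if (.N > 1)
      stats::sd(d_silent_fraction) / sqrt(.N) else NA_real_,
    d_responder_mean_delta_ca = mean(d_responder_mean_delta_ca, na.rm = TRUE)),
    by = by_cond]
  list(per_neuron = merged, overall = overall)
}
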