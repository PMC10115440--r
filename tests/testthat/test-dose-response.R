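test_that("expected influx scales with the concentration ratio", {
  expect_equal(expected_proportional_delta(42, 1.2, 1.2), 42)
  expect_equal(expected_proportional_delta(100, 2.0, 1.2), 60)
  expect_equal(expected_proportional_delta(60, 2.0, 0.8), 24)
  expect_error(expected_proportional_delta(1, 0, 1), "must be > 0")
})

test_that("linear fit recovers exact lines and their x-intercept", {
  ca <- c(0.8, 1.2, 2.0)
  y <- 39.2 * (ca - 0.47)
  f <- fit_linear_intercept(ca, y)
  expect_equal(f$intercept_x, 0.47, tolerance = 1e-12)
  expect_equal(f$slope, 39.2, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  # scaling y leaves the root unchanged
  f2 <- fit_linear_intercept(ca, 2 * y)
  expect_equal(f2$intercept_x, 0.47, tolerance = 1e-12)
  expect_error(fit_linear_intercept(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_warning(fit_linear_intercept(c(1, 2, 3), c(3, 2, 1)),
                 "non-positive slope")
})

test_that("noisy per-neuron linear data recover the intercept closely", {
  set.seed(17)
  ca <- rep(c(0.8, 1.2, 2.0), each = 9)
  ints <- replicate(100, {
    y <- 39.2 * (ca - 0.47) + rnorm(length(ca), 0, 3)
    fit_linear_intercept(ca, y)$intercept_x
  })
  expect_lt(abs(mean(ints) - 0.47), 0.02)
})

test_that("silencing slope matches its printed-arithmetic anchors", {
  expect_equal(silencing_slope(50, 50, 0.8, 1.2), 0)
  expect_equal(silencing_slope(60, 40.44, 0.8, 1.2), 48.9)
  expect_equal(silencing_slope(93, 93 - 29.32, 0.4, 0.8), 73.3)
  expect_error(silencing_slope(1, 2, 1.2, 0.8), "ca_low < ca_high")
})

test_that("constrained Hill fit is exact on model-generated data", {
  d <- c(5, 10, 20, 40, 80, 160)
  s <- 100 * 23^1.46 / (23^1.46 + d^1.46)
  f <- fit_hill_silencing(d, s)
  expect_lt(abs(f$kd - 23) / 23, 1e-6)
  expect_lt(abs(f$coeff - 1.46) / 1.46, 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$coeff_report, -f$coeff)
})

test_that("the fitted maximum is pinned to 100% at zero influx", {
  d <- c(0, 10, 30, 90)
  s <- c(97, 70, 35, 12)
  f <- fit_hill_silencing(d, s)
  # model value at zero influx is 100 by construction for any parameters
  expect_equal(100 * f$kd^f$coeff / (f$kd^f$coeff + 0^f$coeff), 100)
})

test_that("degenerate Hill inputs error informatively", {
  expect_error(fit_hill_silencing(c(25, 25, 25), c(50, 50, 50)),
               "insufficient spread")
  expect_error(fit_hill_silencing(c(1, 2), c(90, 80)), ">= 3")
})

test_that("weighted Hill fit favours high-weight points", {
  d <- c(5, 10, 20, 40, 80)
  s <- 100 * 25^1.79 / (25^1.79 + d^1.79)
  s_off <- s; s_off[5] <- s[5] + 30   # corrupt one point
  f_uw <- fit_hill_silencing(d, s_off)
  f_w <- fit_hill_silencing(d, s_off, weights = c(1, 1, 1, 1, 1e-6))
  expect_lt(abs(f_w$kd - 25), abs(f_uw$kd - 25))
})

test_that("condition summaries reduce terminals to neuron-level statistics", {
  m <- data.table::data.table(
    neuron_id = rep(c("a", "b"), each = 10),
    terminal_id = sprintf("t%02d", 1:20),
    condition_mM = 1.2, modality = "physin-gcamp",
    f_baseline = 50, sigma_baseline = 1, df_peak = 5, f_max = 2000,
    silent = rep(c(TRUE, FALSE), c(4, 6)),
    response_norm = NA_real_, delta_ca_nM = 30,
    saturated = FALSE, subfloor = FALSE, usable = TRUE)
  m[neuron_id == "b", silent := rep(c(TRUE, FALSE), c(6, 4))]
  m[silent == TRUE, delta_ca_nM := NA_real_]
  s <- summarize_condition(m)
  expect_equal(s$per_neuron$silent_fraction, c(0.4, 0.6))
  # CoV with sample SD: sd(0.4, 0.6)/0.5
  expect_equal(s$per_condition$silent_fraction_cov, 0.282842712475,
               tolerance = 1e-10)
  expect_equal(s$per_condition$responder_mean_delta_ca, 30)
  # all-silent neuron: fraction 1, responder mean flagged NA
  m2 <- data.table::copy(m)[, `:=`(silent = TRUE, delta_ca_nM = NA_real_)]
  s2 <- summarize_condition(m2)
  expect_equal(s2$per_neuron$silent_fraction, c(1, 1))
  expect_true(all(is.na(s2$per_neuron$responder_mean_delta_ca)))
  # no-variability fractions give CoV 0
  expect_equal(summarize_condition(
    m[neuron_id == "a"][rep(1:10, 3)][, neuron_id := rep(c("a", "b", "c"),
                                                         each = 10)]
  )$per_condition$silent_fraction_cov, 0)
  # unusable neurons are excluded and reported
  m3 <- data.table::copy(m)[neuron_id == "b", usable := FALSE]
  s3 <- summarize_condition(m3)
  expect_equal(nrow(s3$per_neuron), 1)
  expect_equal(s3$excluded$neuron_id, "b")
  expect_error(summarize_condition(m[0]), "empty")
})

test_that("ECDFs step correctly and silent distributions track noise only", {
  m <- data.table::data.table(
    neuron_id = "a", terminal_id = "t1", condition_mM = 1.2,
    modality = "physin-gcamp", f_baseline = 0, sigma_baseline = 1,
    df_peak = 7, f_max = 1, silent = FALSE, response_norm = NA_real_,
    delta_ca_nM = 1, saturated = FALSE, subfloor = FALSE, usable = TRUE)
  e <- ecdf_by_class(m)
  expect_equal(e$value, 7)
  expect_equal(e$ecdf, 1)
  # silent-class ΔF is condition-independent in the generator's world
  cfg <- small_config(n_neurons = 1, n_terminals = 200,
                      conditions = c(1.2, 0.8), seed = 23)
  ds <- generate_dataset(cfg)
  mm <- measure_dataset(ds)
  sil <- mm[silent == TRUE & usable == TRUE]
  x <- sil[condition_mM == 1.2, df_peak / sigma_baseline]
  y <- sil[condition_mM == 0.8, df_peak / sigma_baseline]
  ks <- suppressWarnings(stats::ks.test(x, y)$statistic)
  expect_lt(unname(ks), 0.2)
  # responding ΔF shifts right with external calcium
  resp <- mm[silent == FALSE]
  expect_gt(resp[condition_mM == 1.2, stats::median(df_peak / f_max)],
            resp[condition_mM == 0.8, stats::median(df_peak / f_max)])
})

test_that("paired effects difference matched neurons and flag mismatches", {
  pre <- data.table::data.table(
    neuron_id = c("a", "b"), condition_mM = 1.2,
    n_terminals = 100, n_usable = 100,
    silent_fraction = c(0.4, 0.5),
    responder_mean_delta_ca = c(30, 28),
    responder_mean_response_norm = NA_real_, n_responders = 60)
  post <- data.table::copy(pre)
  eff0 <- paired_effect(pre, post)
  expect_equal(eff0$per_neuron$d_silent_fraction, c(0, 0))
  post2 <- data.table::copy(pre)[, silent_fraction := c(0.6, 0.65)]
  eff <- paired_effect(pre, post2)
  expect_equal(eff$overall$d_silent_fraction_mean, 0.175)
  expect_error(paired_effect(pre, post2[neuron_id == "a"]), "b")
})
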