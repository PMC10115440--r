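test_that("simulate_terminal_trace builds the expected noiseless epochs", {
  p <- short_protocol()
  term <- make_terminal()
  tr <- simulate_terminal_trace(term, 2, p, noise = noiseless)
  expect_equal(tr$noisy, tr$noiseless)   # degenerate noise
  expect_length(tr$noiseless, p$total_frames)
  base <- 2000 * 0.0284585798518
  expect_equal(tr$noiseless[seq_len(p$baseline_frames)],
               rep(base, p$baseline_frames), tolerance = 1e-9)
  # calibration plateau at F = f_max
  calib <- p$calibration_window[1] + seq_len(p$calib_frames)
  expect_equal(tr$noiseless[calib], rep(2000, p$calib_frames))
  # evoked transient rises above baseline during the train
  pk <- p$peak_window[1] + seq_len(p$peak_window[2])
  expect_gt(mean(tr$noiseless[pk]), base * 2)
})

test_that("silent terminals evoke no stimulus-locked deflection", {
  p <- short_protocol()
  term <- make_terminal(silent = list("2" = TRUE))
  tr <- simulate_terminal_trace(term, 2, p, noise = noiseless)
  pre_calib <- seq_len(p$calibration_window[1])
  expect_equal(diff(range(tr$noiseless[pre_calib])), 0)
})

test_that("unknown conditions are a key error", {
  expect_error(
    simulate_terminal_trace(make_terminal(), 1.2, short_protocol(),
                            noise = noiseless),
    "unknown condition 1.2")
})

test_that("ground-truth table has n_neurons x n_terminals x conditions rows", {
  ds <- generate_dataset(small_config(n_neurons = 3, n_terminals = 10,
                                      conditions = c(2, 1.2, 0.8)))
  expect_equal(nrow(ds$ground_truth), 3 * 10 * 3)
  expect_setequal(unique(ds$ground_truth$condition_mM), c(2, 1.2, 0.8))
  expect_equal(length(ds$recordings), 3)
  rec <- ds$recordings$neuron01[["2"]]
  expect_equal(dim(rec$noisy), c(short_protocol()$total_frames, 10))
})

test_that("hard-threshold mode silences exactly the sub-threshold influx", {
  cfg <- small_config(conditions = c(2.0, 0.8),
                      silencing = silencing_model(25, 1.79, "hard-threshold"))
  ds <- generate_dataset(cfg)
  gt <- ds$ground_truth
  expect_true(all(gt$silent_true == (gt$delta_ca_true_nM < 25)))
  # influx at 2.0 mM (~60 nM) responds, at 0.8 mM (~12.9 nM) is silent
  expect_false(any(gt$silent_true[gt$condition_mM == 2.0]))
  expect_true(all(gt$silent_true[gt$condition_mM == 0.8]))
})

test_that("perturbation scales influx by (1 - perturbation) before draws", {
  a <- generate_dataset(small_config(seed = 5))
  b <- generate_dataset(small_config(seed = 5, perturbation = 0.4))
  expect_equal(b$ground_truth$delta_ca_true_nM,
               a$ground_truth$delta_ca_true_nM * 0.6)
  # shared seed: the per-terminal silencing draw u is identical, so
  # silencing can only be gained, never lost, under reduced influx
  expect_true(all(b$ground_truth$silent_true >= a$ground_truth$silent_true))
})

test_that("silencing is monotone within terminal across conditions", {
  ds <- generate_dataset(small_config(n_neurons = 2, n_terminals = 100,
                                      conditions = c(2.0, 1.2, 0.8, 0.4)))
  gt <- data.table::as.data.table(ds$ground_truth)
  data.table::setorder(gt, neuron_id, terminal_id, -condition_mM)
  mono <- gt[, all(diff(as.integer(silent_true)) >= 0),
             by = c("neuron_id", "terminal_id")]
  expect_true(all(mono$V1))
})

test_that("empirical silent fraction converges to the configured probability", {
  cfg <- small_config(n_neurons = 1, n_terminals = 3000, conditions = 1.2,
                      seed = 9,
                      geometry = list(width = 512, height = 512,
                                      psf_sigma = 1.5, min_separation = 4,
                                      background = 20, offset = 100))
  ds <- generate_dataset(cfg)
  p <- silencing_probability(influx_at(1.2, cfg$influx), cfg$silencing)
  frac <- mean(ds$ground_truth$silent_true)
  # 95% binomial band around p at n = 3000
  expect_lt(abs(frac - p), 1.96 * sqrt(p * (1 - p) / 3000) + 1e-12)
})

test_that("identical config and seed reproduce the dataset exactly", {
  a <- generate_dataset(small_config(seed = 11))
  b <- generate_dataset(small_config(seed = 11))
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$recordings$neuron02[["0.8"]]$noisy,
                   b$recordings$neuron02[["0.8"]]$noisy)
  c <- generate_dataset(small_config(seed = 12))
  expect_false(identical(a$recordings$neuron01[["2"]]$noisy,
                         c$recordings$neuron01[["2"]]$noisy))
})

test_that("earlier neurons are unchanged when n_neurons grows", {
  a <- generate_dataset(small_config(n_neurons = 2, seed = 4))
  b <- generate_dataset(small_config(n_neurons = 3, seed = 4))
  expect_identical(a$recordings$neuron01[["2"]]$noisy,
                   b$recordings$neuron01[["2"]]$noisy)
  expect_identical(a$ground_truth[neuron_id == "neuron02"],
                   b$ground_truth[neuron_id == "neuron02"])
})

test_that("config validation reports every violation at once", {
  cfg <- small_config()
  cfg$n_neurons <- 0L
  cfg$perturbation <- 1.5
  cfg$resting_ca <- -1
  err <- tryCatch(validate_generator_config(cfg), error = conditionMessage)
  expect_match(err, "n_neurons")
  expect_match(err, "perturbation")
  expect_match(err, "resting_ca")
})

test_that("vGpH and iGluSnFR traces normalize as constructed", {
  # vGpH: responder releasing resp_frac of the NH4Cl-revealed pool
  pv <- stimulus_protocol("vgph", post_frames = 10, gap_frames = 2,
                          calib_frames = 10)
  term <- make_terminal(resp = list("2" = 0.3))
  tr <- simulate_terminal_trace(term, 2, pv, default_sensor("vgph"),
                                noiseless)
  m <- measure_recording(matrix(tr$noisy, ncol = 1), pv,
                         neuron_id = "n", condition = 2)
  expect_equal(m$response_norm, 0.3, tolerance = 0.03)
  expect_false(m$silent)
  # iGluSnFR: 15 single-AP trials averaged; reference is F_max itself
  pi <- stimulus_protocol("iglusnfr", calib_frames = 10, gap_frames = 2)
  term$resp_frac <- list("2" = 0.2)
  tri <- simulate_terminal_trace(term, 2, pi, default_sensor("iglusnfr"),
                                 noiseless)
  mi <- measure_recording(matrix(tri$noisy, ncol = 1), pi,
                          neuron_id = "n", condition = 2)
  # 5% kinetics-limited tolerance: the first peak frame still sits on the
  # rising phase of the 2 ms transient
  expect_equal(mi$response_norm, 0.2, tolerance = 0.05)
})
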