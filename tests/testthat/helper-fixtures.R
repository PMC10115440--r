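# shared fixtures: small protocols and generator configs for fast tests

short_protocol <- function(...) {
  stimulus_protocol("physin-gcamp", post_frames = 20, gap_frames = 5,
                    calib_frames = 10, ...)
}

small_config <- function(n_neurons = 2, n_terminals = 30,
                         conditions = c(2.0, 0.8), seed = 1, ...) {
  generator_config(n_neurons = n_neurons,
                   n_terminals_per_neuron = n_terminals,
                   ca_e_conditions = conditions,
                   protocol = short_protocol(), seed = seed, ...)
}

noiseless <- list(read_sd = 0, shot_scale = 0)

# a bare ground-truth terminal for simulate_terminal_trace
make_terminal <- function(f_max = 2000, resting_ca = 0.05,
                          delta = list("2" = 59.976),
                          silent = list("2" = FALSE),
                          baseline_frac = 0.06, resp = list("2" = 0.3)) {
  list(f_max = f_max, resting_ca = resting_ca, delta_ca_true = delta,
       silent_true = silent, baseline_frac = baseline_frac,
       resp_frac = resp)
}

# render a clean single-frame image with unit-trace spots
spot_image <- function(positions, amplitudes, width = 64, height = 64,
                       psf_sigma = 1.5, background = 0, offset = 100) {
  geo <- list(width = width, height = height, psf_sigma = psf_sigma,
              min_separation = 4, background = background, offset = offset)
  traces <- matrix(amplitudes, nrow = 1)
  render_movie(positions, traces, geo)[, , 1]
}
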