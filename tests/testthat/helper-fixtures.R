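# Heavyweight fixtures shared across test files, built once per run.
fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = fixture_cache))
    assign(name, build(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# miniature torus network for protocol/unit tests (400 + 400 neurons)
small_conn <- function() connectivity_config(grid_side = 20, sigma_E = 4,
                                             sigma_I = 5)
small_network <- function() fx("small_network",
                               function() build_network(small_conn(),
                                                        seed = 42))

# full-scale baseline network + calibrated weights for acceptance tests
full_network <- function() fx("full_network",
                              function() build_network(connectivity_config(),
                                                       seed = 42))
default_neuron <- function() neuron_params()
default_synapse <- function() synapse_params()
default_weights <- function() fx("default_weights", function()
  calibrate_weights(default_synapse(), default_neuron()))

# noise-free synthetic clamp fixture with alpha-shaped ground truth
clamp_fixture <- function(peak_ge = 1.7, peak_gi = 0.53, noise_sd = 0,
                          n_sweeps = 1, seed = 1) {
  truth <- example_ground_truth("center", t_on = 100, peak_ge = peak_ge,
                                peak_gi = peak_gi, t_max = 250, dt = 0.5)
  cfg <- clamp_sim_config(noise_sd = noise_sd, n_sweeps = n_sweeps,
                          seed = seed)
  list(truth = truth, cfg = cfg,
       traces = simulate_clamp_currents(truth, cfg))
}

# bare-bones stand-in for a trial recording (trace averaging / rate tests)
mock_trial <- function(time, ge, spikes = NULL, N_E = 6400, N_I = 6400) {
  structure(list(time = time, ge = ge, gi = ge * 0, V = ge * 0,
                 spikes = spikes %||%
                   data.frame(id = integer(), pop = character(),
                              time = numeric()),
                 N_E = N_E, N_I = N_I),
            class = "trial_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
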