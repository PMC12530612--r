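test_that("alpha waveform has the canonical shape and rescaling contract", {
  t <- seq(0, 60, by = 0.1)
  w <- alpha_waveform(2, onset = 10, tau = 3, time = t)
  expect_equal(t[which.max(w)], 13)            # peak one tau after onset
  expect_equal(max(w), 2, tolerance = 1e-9)    # peak equals the amplitude
  expect_true(all(w[t <= 10] == 0))
  expect_true(all(diff(w[t > 13]) < 0))        # monotone decay past the peak
  expect_identical(alpha_waveform(0, 10, 3, t), rep(0, length(t)))
  expect_error(alpha_waveform(1, 10, -1, t), "tau")
  expect_error(alpha_waveform(1, 100, 3, t), "onset")
})

test_that("clamp forward model reproduces hand-computed currents", {
  time <- c(0, 0.5, 1)
  truth <- ground_truth_conductance(time, ge = c(0, 2, 0), gi = c(0, 1, 0))
  cfg <- clamp_sim_config(holding = c(-65, 0), junction = -10,
                          reversal_e = -10, reversal_i = -75, noise_sd = 0)
  cts <- simulate_clamp_currents(truth, cfg)
  # V_corr = -75: I = ge * (-75 - (-10)) = 2 * (-65) = -130 pA
  expect_equal(cts$traces[[1]][2, 1], -130)
  # V_corr = -10: I = gi * (-10 - (-75)) = 1 * 65 = +65 pA
  expect_equal(cts$traces[[2]][2, 1], 65)
  # zero conductances, zero noise -> identically zero currents
  z <- simulate_clamp_currents(
    ground_truth_conductance(time, c(0, 0, 0), c(0, 0, 0)), cfg)
  expect_true(all(vapply(z$traces, function(m) all(m == 0), logical(1))))
})

test_that("clamp simulation is bit-reproducible under a fixed seed", {
  fxt <- clamp_fixture(noise_sd = 5, n_sweeps = 3, seed = 99)
  again <- simulate_clamp_currents(fxt$truth, fxt$cfg)
  expect_identical(fxt$traces$traces, again$traces)
})

test_that("ground truth and clamp configs validate their invariants", {
  expect_error(ground_truth_conductance(c(0, 1, 3), c(0, 0, 0), c(0, 0, 0)),
               "constant")
  expect_error(ground_truth_conductance(c(0, 1), c(-1, 0), c(0, 0)),
               "nonnegative")
  expect_error(clamp_sim_config(holding = c(-65, -65)), "distinct")
  expect_error(clamp_sim_config(noise_sd = -1), "noise_sd")
})

test_that("synthetic zone maps follow the Gaussian sensitivity profile", {
  cfg <- zone_map_sim_config(profile_center = c(5, 5), profile_sigma = 2,
                             peak_amplitude = 100, noise_sd = 0)
  zm <- simulate_zone_map(cfg)
  expect_equal(zm$amplitudes[5, 5], 100)
  # cell at grid distance 2: peak * exp(-4 / (2*4)) = peak * exp(-1/2)
  expect_equal(zm$amplitudes[5, 7], 100 * exp(-0.5), tolerance = 1e-12)
  # near-degenerate width: a single responsive cell
  tight <- simulate_zone_map(zone_map_sim_config(profile_center = c(5, 5),
                                                 profile_sigma = 0.05,
                                                 peak_amplitude = 100,
                                                 noise_sd = 0))
  expect_equal(sum(tight$amplitudes > 1e-12), 1)
  # noise never produces negative amplitudes, seed reproducible
  noisy1 <- simulate_zone_map(zone_map_sim_config(noise_sd = 30, seed = 5))
  noisy2 <- simulate_zone_map(zone_map_sim_config(noise_sd = 30, seed = 5))
  expect_true(all(noisy1$amplitudes >= 0))
  expect_identical(noisy1$amplitudes, noisy2$amplitudes)
})
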