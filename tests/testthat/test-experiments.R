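test_that("trial averaging collapses for identical trials and is exact for two", {
  t <- seq(0.1, 10, by = 0.1)
  g <- alpha_waveform(2, 1, 2, t)
  same <- replicate(5, mock_trial(t, g), simplify = FALSE)
  avg <- average_trials(same)
  expect_equal(avg$mean, g)
  expect_equal(avg$q25, g)
  expect_equal(avg$q75, g)
  two <- list(mock_trial(t, g), mock_trial(t, g + 1))
  expect_equal(average_trials(two)$mean, g + 0.5)
  expect_error(average_trials(list(mock_trial(t, g),
                                   mock_trial(t + 1, g))),
               "time axis")
  expect_error(average_trials(same[1]), "trials")
})

test_that("quartile band matches the normal quantiles of injected noise", {
  t <- seq(0.1, 5, by = 0.1)
  set.seed(20)
  trials <- lapply(1:800, function(i) mock_trial(t, 10 + rnorm(length(t), 0, 2)))
  avg <- average_trials(trials)
  half_band <- mean(avg$q75 - avg$q25) / 2
  expect_equal(half_band, qnorm(0.75) * 2, tolerance = 0.05)
})

test_that("peak splitting recovers constructed two-alpha responses exactly", {
  t <- seq(0.1, 80, by = 0.1)
  mono <- alpha_waveform(3, 20, 2, t)      # peaks at 22
  netw <- alpha_waveform(5, 30, 4, t)      # peaks at 34
  pd <- split_peaks(mono + netw, t, T_center = 20, boundary = 5)
  expect_equal(pd$first_time, 22, tolerance = 0.2)
  expect_equal(pd$first_peak, max((mono + netw)[t <= 25]))
  expect_equal(pd$second_time, t[which.max(mono + netw)][1], tolerance = 2)
  expect_false(pd$low_amplitude)
  # flat network window is flagged, not an error
  flat <- split_peaks(mono, t, T_center = 20, boundary = 15)
  expect_true(flat$low_amplitude)
  expect_error(split_peaks(mono, t, T_center = 20, boundary = 0), "boundary")
  expect_error(split_peaks(mono, t, T_center = 79, boundary = 5), "beyond")
})

test_that("suppression ratio arithmetic and undefined flag", {
  pd <- function(second) structure(list(first_peak = 1, second_peak = second),
                                   class = "peak_decomposition")
  expect_equal(suppression_ratio(pd(2), pd(2))$ratio, 1)
  sr <- suppression_ratio(pd(1), pd(2))
  expect_equal(sr$ratio, 0.5)
  expect_equal(sr$percent_suppression, 50)
  expect_true(suppression_ratio(pd(1), pd(0))$undefined)
})

test_that("a 1x1 sweep equals a direct two-condition comparison", {
  net <- small_network()
  neu <- default_neuron(); syn <- default_synapse()
  sw <- run_sweep(net, syn, neu, J_ie_values = syn$J[["ie"]],
                  J_ei_values = syn$J[["ei"]], J_ee = syn$J[["ee"]],
                  n_trials = 4, seed = 3,
                  protocol_args = list(center_radius = 3, center_count = 29,
                                       square_side = 15))
  expect_equal(dim(sw$ratio), c(1, 1))
  expect_true(is.finite(sw$ratio[1, 1]))
  expect_equal(sw$percent_suppression[1, 1], 100 * (1 - sw$ratio[1, 1]))
  # same topology, weights and seeds -> reproducible
  sw2 <- run_sweep(net, syn, neu, J_ie_values = syn$J[["ie"]],
                   J_ei_values = syn$J[["ei"]], J_ee = syn$J[["ee"]],
                   n_trials = 4, seed = 3,
                   protocol_args = list(center_radius = 3, center_count = 29,
                                        square_side = 15))
  expect_identical(sw$ratio, sw2$ratio)
})
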