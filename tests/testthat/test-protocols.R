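test_that("center selection is geometric, exact, and seed-free", {
  idx <- select_center(80, radius = 10, count = 314)
  expect_length(idx, 314)
  expect_true(all(attr(idx, "distance") <= 10))
  expect_identical(unclass(idx), unclass(select_center(80, 10, 314)))
  one <- select_center(80, radius = 10, count = 1)
  expect_length(one, 1)
  expect_lt(attr(one, "distance"), 1)
  expect_error(select_center(80, radius = 2, count = 314), "cannot select")
})

test_that("surround selection realizes the 60^2 - 314 arithmetic", {
  center <- select_center(80)
  surround <- select_surround(80, 60, center)
  expect_length(surround, 3600 - 314)
  expect_length(intersect(surround, center), 0)
  # center plus surround exactly tile the 60 x 60 square
  expect_length(select_surround(80, 60, integer()), 3600)
  expect_setequal(c(surround, center), select_surround(80, 60, integer()))
  expect_error(select_surround(20, 60, center), "larger")
})

test_that("center volley events carry the jittered compound retinal input", {
  center <- select_center(80)
  set.seed(11)
  ev <- make_center_volley(center, 6400, T_center = 100, w_retinal = 0.8)
  expect_equal(nrow(ev), 2 * 314)            # both populations
  expect_true(all(ev$time >= 100 & ev$time <= 101))
  expect_true(all(ev$amount == 10 * 0.8))
  expect_setequal(ev$id, c(center, 6400 + center))
  set.seed(11)
  expect_identical(ev, make_center_volley(center, 6400, 100, 0.8))
})

test_that("surround Poisson drive has the right mass and window", {
  surround <- select_surround(80, 60, select_center(80))
  set.seed(12)
  ev <- make_surround_drive(surround, 6400, window = c(60, 80), rate = 100,
                            w_retinal = 0.8)
  lambda <- 2 * 3286 * 100 * 0.020
  expect_lt(abs(nrow(ev) - lambda), 3 * sqrt(lambda))
  expect_true(all(ev$time >= 60 & ev$time <= 80))
  none <- make_surround_drive(surround, 6400, c(60, 80), 0, 0.8)
  expect_equal(nrow(none), 0)
  expect_error(make_surround_drive(surround, 6400, c(60, 80), -1, 0.8),
               "rate")
})

test_that("silent inputs leave the network at rest", {
  net <- small_network()
  prot <- stimulus_protocol("surround_only", surround_rate = 0,
                            surround_window = c(0, 0), t_stop = 100,
                            center_radius = 3, center_count = 29,
                            square_side = 15, bg_rate_ex = 0, bg_rate_ix = 0)
  tr <- run_trial(net, default_weights(), default_synapse(),
                  default_neuron(), prot, seed = 1,
                  record_neuron = select_center(20, 3, 29)[1])
  expect_equal(nrow(tr$spikes), 0)
  expect_true(all(abs(tr$V - default_neuron()$E_L) < 1e-9))
  expect_true(all(tr$ge == 0))
})

test_that("trials are bit-identical under the trial seed", {
  net <- small_network()
  prot <- stimulus_protocol("center_after_surround", T_center = 60,
                            t_stop = 100, center_radius = 3,
                            center_count = 29, square_side = 15,
                            bg_rate_ex = 1425, bg_rate_ix = 400)
  rec <- select_center(20, 3, 29)[1]
  a <- run_trial(net, default_weights(), default_synapse(), default_neuron(),
                 prot, seed = 5, record_neuron = rec)
  b <- run_trial(net, default_weights(), default_synapse(), default_neuron(),
                 prot, seed = 5, record_neuron = rec)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ge, b$ge)
  d <- run_trial(net, default_weights(), default_synapse(), default_neuron(),
                 prot, seed = 6, record_neuron = rec)
  expect_false(identical(a$spikes, d$spikes))
  expect_true(all(a$spikes$time <= 100))
  expect_error(run_trial(net, default_weights(), default_synapse(),
                         default_neuron(), prot, seed = 5,
                         record_neuron = 399L),
               "center")
})

test_that("protocol invariants on timing are enforced", {
  expect_error(stimulus_protocol("center_during_surround", T_center = 200,
                                 surround_window = c(60, 80)),
               "inside")
  expect_error(stimulus_protocol("center_after_surround", T_center = 70,
                                 surround_window = c(60, 80)),
               "after")
  p <- stimulus_protocol("center_after_surround", T_center = 100)
  expect_equal(p$surround_window, c(80, 100))
  expect_error(stimulus_protocol("center_only", surround_rate = -5), "rate")
})

test_that("population rates do the spikes-per-neuron-per-second arithmetic", {
  spk <- data.frame(id = 0:6399, pop = "E",
                    time = runif(6400, 0, 1000))
  tr <- mock_trial(time = seq(0.1, 1000, by = 0.1), ge = numeric(10000),
                   spikes = spk)
  r <- population_rates(tr, c(0, 1000))
  expect_equal(r$rate_E, 1)
  expect_equal(r$rate_I, 0)
  expect_error(population_rates(tr, c(5, 5)), "window")
})
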