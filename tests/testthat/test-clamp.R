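test_that("junction correction shifts commanded potentials only", {
  fxt <- clamp_fixture()
  corr <- correct_junction(fxt$traces)
  expect_equal(corr$holding, c(-75, -10))
  expect_identical(corr$traces, fxt$traces$traces)
  expect_warning(correct_junction(corr), "already")
  ident <- clamp_trace_set(fxt$truth$time, fxt$traces$traces, c(-65, 0),
                           junction = 0)
  expect_equal(correct_junction(ident)$holding, c(-65, 0))
})

test_that("decomposition inverts the two-potential forward model by hand", {
  time <- c(0, 0.5, 1)
  cts <- clamp_trace_set(time,
                         list(c(0, -130, 0), c(0, 65, 0)),
                         holding = c(-65, 0), junction = -10)
  est <- decompose_conductances(cts, reversal_e = -10, reversal_i = -75,
                                t_c = 0, baseline_window = NULL)
  expect_equal(est$ge[2], 2, tolerance = 1e-12)
  expect_equal(est$gi[2], 1, tolerance = 1e-12)
  expect_equal(est$gt, est$ge + est$gi)
  zero <- decompose_conductances(
    clamp_trace_set(time, list(rep(0, 3), rep(0, 3)), c(-65, 0)),
    t_c = 0, baseline_window = NULL)
  expect_true(all(zero$ge == 0) && all(zero$gi == 0) && all(zero$gt == 0))
})

test_that("noise-free synthetic round trip recovers ground truth to 1e-9", {
  for (seed in 1:3) {
    set.seed(seed)
    truth <- ground_truth_conductance(
      seq(0, 250, by = 0.5),
      alpha_waveform(runif(1, 0.5, 3), 100, runif(1, 5, 15),
                     seq(0, 250, by = 0.5)),
      alpha_waveform(runif(1, 0.2, 1), 105, runif(1, 8, 20),
                     seq(0, 250, by = 0.5)))
    cts <- simulate_clamp_currents(truth,
                                   clamp_sim_config(noise_sd = 0, seed = seed))
    est <- decompose_conductances(cts, t_c = 100)
    scale <- max(truth$ge)
    expect_lt(max(abs(est$ge - truth$ge)) / scale, 1e-9)
    expect_lt(max(abs(est$gi - truth$gi)) / max(truth$gi), 1e-9)
    expect_identical(est$gt, est$ge + est$gi)
    expect_false(est$flags$negative_ge)
  }
})

test_that("baseline subtraction makes the estimate leak-invariant", {
  fxt <- clamp_fixture()
  shifted <- fxt$traces
  shifted$traces[[1]] <- shifted$traces[[1]] + 37   # constant holding current
  shifted$traces[[2]] <- shifted$traces[[2]] - 12
  a <- decompose_conductances(fxt$traces, t_c = 100)
  b <- decompose_conductances(shifted, t_c = 100)
  expect_equal(a$ge, b$ge, tolerance = 1e-9)
  expect_equal(a$gi, b$gi, tolerance = 1e-9)
})

test_that("sweep averaging shrinks the bias of noisy peak estimates", {
  truth <- example_ground_truth("center", t_on = 100, t_max = 250, dt = 0.5)
  err <- function(n_sweeps) {
    e <- vapply(1:12, function(s) {
      cts <- simulate_clamp_currents(truth,
        clamp_sim_config(noise_sd = 20, n_sweeps = n_sweeps, seed = 1000 + s))
      est <- decompose_conductances(cts, t_c = 100)
      abs(est$peak_ge - max(truth$ge))
    }, numeric(1))
    mean(e)
  }
  expect_lt(err(50), err(5))
})

test_that("peak latency follows the argmax with earliest-tie rule", {
  t <- seq(0, 60, by = 0.1)
  w <- alpha_waveform(1, onset = 10, tau = 3, time = t)
  pl <- peak_latency(w, t, t0 = 10)
  expect_equal(pl$latency, 3, tolerance = 0.1)
  expect_false(pl$no_peak)
  flat <- peak_latency(rep(2, length(t)), t, t0 = 0)
  expect_true(flat$no_peak)
  expect_true(is.na(flat$latency))
  two <- numeric(length(t))
  two[t == 5] <- 1; two[t == 9] <- 1
  expect_equal(peak_latency(two, t, t0 = 0)$latency, 5)
  expect_error(peak_latency(w, t, t0 = 100), "t0")
})

test_that("suppression stats reproduce the printed exemplar classification", {
  mk <- function(peak_ge, peak_gi = 0.53) {
    truth <- example_ground_truth("center", t_on = 100, peak_ge = peak_ge,
                                  peak_gi = peak_gi, t_max = 250, dt = 0.5)
    decompose_conductances(
      simulate_clamp_currents(truth, clamp_sim_config(noise_sd = 0)),
      t_c = 100)
  }
  c1 <- mk(1.7); cs <- mk(0.6)
  sup <- suppression_stats(c1, cs)
  expect_equal(sup$reduction_fraction, 1 - 0.6 / 1.7, tolerance = 1e-6)
  expect_identical(sup$category, "strong")
  same <- suppression_stats(c1, c1)
  expect_equal(same$reduction_fraction, 0, tolerance = 1e-9)
  expect_identical(same$category, "mild")
  # boundary rule: exactly 60% is moderate (inclusive), just above is strong
  expect_identical(classify_suppression(0.60), "moderate")
  expect_identical(classify_suppression(0.60 + 1e-9), "strong")
  expect_identical(classify_suppression(0.20), "moderate")
  expect_identical(classify_suppression(0.20 - 1e-9), "mild")
})

test_that("iso-conductance trajectory is a plain time-ordered pairing", {
  fxt <- clamp_fixture()
  est <- decompose_conductances(fxt$traces, t_c = 100)
  traj <- iso_conductance_trajectory(est)
  expect_identical(traj$ge, est$ge)
  expect_identical(traj$gi, est$gi)
  expect_identical(traj$time, est$time)
})

test_that("negative excursions under noise are flagged, not clipped", {
  time <- c(0, 0.5, 1)
  # currents implying a negative conductance at the middle sample
  est <- decompose_conductances(
    clamp_trace_set(time, list(c(0, 130, 0), c(0, -65, 0)), c(-65, 0)),
    t_c = 0, baseline_window = NULL)
  expect_true(est$flags$negative_ge || est$flags$negative_gi)
  expect_true(any(est$ge < 0) || any(est$gi < 0))
})
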