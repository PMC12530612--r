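test_that("torus distance wraps per axis", {
  expect_equal(torus_distance(c(0, 0), c(0, 0), 80), 0)
  expect_equal(torus_distance(c(0, 0), c(79, 0), 80), 1)
  expect_equal(torus_distance(c(0, 0), c(40, 30), 80), 50)
  expect_equal(torus_distance(c(0, 0), c(41, 0), 80), 39)
  expect_error(torus_distance(c(0, 0), c(80, 0), 80), "side")
})

test_that("Gaussian kernel probability and mass calibration", {
  expect_equal(connection_probability(0, 16, 0.5), 0.5)
  expect_equal(connection_probability(0, 16, 0.5) /
                 connection_probability(16, 16, 0.5),
               exp(0.5), tolerance = 1e-12)
  expect_warning(connection_probability(0, 16, 1.2), "capped")
  # kernel mass over the torus realizes the requested mean probability
  side <- 20; sigma <- 4; p_mean <- 0.2
  s <- kernel_scale(p_mean, sigma, side)
  off <- 0:(side - 1); w <- pmin(off, side - off)
  mass <- s * sum(exp(-outer(w^2, w^2, "+") / (2 * sigma^2)))
  expect_equal(mass / side^2, p_mean, tolerance = 1e-12)
})

test_that("realized degrees match the binomial expectation within 3 SE", {
  net <- small_network()
  side <- 20
  for (cl in c("ee", "ie")) {
    K <- small_conn()$p[[cl]] * side^2        # expected out-degree
    deg <- out_degrees(net, cl)
    se <- sqrt(K / length(deg))               # conservative binomial SE
    expect_lt(abs(mean(deg) - K), 3 * se + K * 2.5e-3)
    indeg <- in_degrees(net, cl)
    expect_lt(abs(mean(indeg) - K), 3 * se + K * 2.5e-3)
  }
})

test_that("degenerate kernels give empty or complete graphs", {
  empty <- build_network(connectivity_config(grid_side = 8, sigma_E = 2,
                                             sigma_I = 2,
                                             p = c(ee = 0, ei = 0,
                                                   ie = 0, ii = 0)),
                         seed = 1)
  expect_true(all(vapply(empty$adjacency,
                         function(a) length(a$targets) == 0, logical(1))))
  # near-flat kernel at p_mean 1: complete directed graph, no self-edges
  # (the marginally-above-1 scale warning is expected here)
  full <- suppressWarnings(
    build_network(connectivity_config(grid_side = 6, sigma_E = 1e6,
                                      sigma_I = 1e6,
                                      p = c(ee = 1, ei = 1,
                                            ie = 1, ii = 1)),
                  seed = 1))
  N <- 36
  expect_equal(length(full$adjacency$ee$targets), N * (N - 1))
  expect_equal(length(full$adjacency$ei$targets), N * N)
  self <- function(adj) {
    pre <- rep(seq_len(N) - 1L, diff(adj$row_ptr))
    any(pre == adj$targets)
  }
  expect_false(self(full$adjacency$ee))
  expect_false(self(full$adjacency$ii))
})

test_that("network sampling is reproducible under the seed", {
  a <- build_network(small_conn(), seed = 7)
  b <- build_network(small_conn(), seed = 7)
  expect_identical(a$adjacency, b$adjacency)
  c <- build_network(small_conn(), seed = 8)
  expect_false(identical(a$adjacency$ee$targets, c$adjacency$ee$targets))
  d <- rebuild_class(a, "ee", 0.05, seed = 9)
  expect_identical(d$adjacency$ie, a$adjacency$ie)
  expect_lt(mean(out_degrees(d, "ee")), mean(out_degrees(a, "ee")))
})

test_that("PSP calibration hits the requested amplitude", {
  neu <- default_neuron(); syn <- default_synapse()
  expect_equal(calibrate_weight(0, 3, 0, neu), 0)
  w_ret <- calibrate_weight(1.1, syn$tau[["ex"]], syn$E_rev_exc, neu)
  expect_lt(abs(psp_peak(w_ret, syn$tau[["ex"]], syn$E_rev_exc, neu) - 1.1),
            0.0011)
  # inhibitory calibration against the hyperpolarization magnitude
  w_inh <- calibrate_weight(0.4, 5, syn$E_rev_inh, neu)
  expect_lt(abs(psp_peak(w_inh, 5, syn$E_rev_inh, neu) - 0.4), 4e-4)
  # near-linear subthreshold regime: doubling J about doubles the weight
  w1 <- calibrate_weight(0.13, 3, 0, neu)
  w2 <- calibrate_weight(0.26, 3, 0, neu)
  expect_equal(w2 / w1, 2, tolerance = 0.02)
  expect_error(calibrate_weight(1, 3, neu$E_L, neu), "reversal")
})

test_that("membrane dynamics match the closed-form leak solution", {
  neu <- default_neuron()
  # rest is a fixed point
  expect_equal(psp_peak(0, 3, 0, neu), 0)
  # displaced membrane relaxes with tau_m = C_m / g_L
  tr <- scsurround:::cpp_single_trace(3000, 0.1, neu$C_m, neu$g_L, neu$E_L,
                                      neu$E_L + 5, integer(0), numeric(0),
                                      3, 0)
  tau_m <- neu$C_m / neu$g_L
  t <- seq_len(3000) * 0.1
  expect_lt(max(abs(tr$V - (neu$E_L + 5 * exp(-t / tau_m)))) / 5, 1e-3)
})

test_that("integrator converges and conductances superpose linearly", {
  neu <- default_neuron()
  p1 <- psp_peak(0.5, 3, 0, neu, dt = 0.1)
  p2 <- psp_peak(0.5, 3, 0, neu, dt = 0.05)
  expect_lt(abs(p1 - p2) / p2, 0.005)
  # g responds linearly to spikes (V does not need to)
  one <- scsurround:::cpp_single_trace(1000, 0.1, neu$C_m, neu$g_L, neu$E_L,
                                       neu$E_L, 50L, 0.5, 3, 0)
  other <- scsurround:::cpp_single_trace(1000, 0.1, neu$C_m, neu$g_L,
                                         neu$E_L, neu$E_L, 300L, 0.5, 3, 0)
  both <- scsurround:::cpp_single_trace(1000, 0.1, neu$C_m, neu$g_L, neu$E_L,
                                        neu$E_L, c(50L, 300L), c(0.5, 0.5),
                                        3, 0)
  expect_equal(both$g, one$g + other$g, tolerance = 1e-12)
})

test_that("conductance synapses respect their reversal potentials", {
  neu <- default_neuron()
  big_exc <- scsurround:::cpp_single_trace(2000, 0.1, neu$C_m, neu$g_L,
                                           neu$E_L, neu$E_L, 10L, 500, 3, 0)
  expect_true(all(big_exc$V <= 0 + 1e-9))
  big_inh <- scsurround:::cpp_single_trace(2000, 0.1, neu$C_m, neu$g_L,
                                           neu$E_L, neu$E_L, 10L, 500, 5, -80)
  expect_true(all(big_inh$V >= -80 - 1e-9))
})
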