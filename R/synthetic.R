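#' Alpha conductance waveform
#'
#' Canonical synthetic conductance shape: zero before \code{onset}, rising
#' to its maximum exactly one time constant after onset, then decaying.
#' The function is rescaled so its peak equals \code{amplitude}:
#' \deqn{g(t) = A \frac{t - t_0}{\tau} \exp(1 - (t - t_0)/\tau).}
#'
#' @param amplitude peak conductance (nS, >= 0).
#' @param onset waveform onset \eqn{t_0} (ms), within \code{time}.
#' @param tau time constant (ms, > 0).
#' @param time time axis (ms).
#' @return numeric waveform (nS) along \code{time}.
#' @examples
#' t <- seq(0, 60, by = 0.1)
#' w <- alpha_waveform(2, onset = 10, tau = 3, time = t)
#' t[which.max(w)]  # 13: peak one tau after onset
#' @export
alpha_waveform <- function(amplitude, onset, tau, time) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (onset < min(time) || onset > max(time))
    stop("onset must lie within the time axis", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  s <- (time - onset) / tau
  ifelse(s > 0, amplitude * s * exp(1 - s), 0)
}

#' Ground-truth conductance pair
#'
#' Container for the known excitatory/inhibitory conductance time courses
#' behind a synthetic voltage-clamp recording.
#'
#' @param time uniform time axis (ms).
#' @param ge,gi nonnegative conductances (nS) along \code{time}.
#' @param description free-text label.
#' @return an object of class \code{"ground_truth_conductance"}.
#' @export
ground_truth_conductance <- function(time, ge, gi, description = "") {
  errs <- character()
  if (length(time) < 2) errs <- c(errs, "time axis needs >= 2 points")
  dts <- diff(time)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * max(dts))
    errs <- c(errs, "time step must be strictly positive and constant")
  if (length(ge) != length(time) || length(gi) != length(time))
    errs <- c(errs, "ge and gi must share the time axis length")
  if (any(ge < 0) || any(gi < 0))
    errs <- c(errs, "ge and gi must be nonnegative everywhere")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(time = time, ge = ge, gi = gi, description = description),
            class = "ground_truth_conductance")
}

#' Example ground-truth waveforms with realistic latencies
#'
#' Alpha-shaped excitatory and inhibitory conductances whose peaks fall at
#' the latencies reported for slice responses: center-like responses peak
#' at 9 ms (excitation) and 15 ms (inhibition) after stimulus onset,
#' surround-like responses at 20 and 28 ms.
#'
#' @param type \code{"center"} or \code{"surround"}.
#' @param t_on stimulus onset (ms).
#' @param peak_ge,peak_gi peak conductances (nS); defaults are the reported
#'   center-only means (1.7 and 0.53 nS).
#' @param t_max end of the time axis (ms).
#' @param dt time step (ms).
#' @return a \code{\link{ground_truth_conductance}}.
#' @export
example_ground_truth <- function(type = c("center", "surround"), t_on = 100,
                                 peak_ge = 1.7, peak_gi = 0.53,
                                 t_max = 300, dt = 0.1) {
  type <- match.arg(type)
  lat <- if (type == "center") c(e = 9, i = 15) else c(e = 20, i = 28)
  time <- seq(0, t_max, by = dt)
  ground_truth_conductance(
    time,
    alpha_waveform(peak_ge, t_on, lat[["e"]], time),
    alpha_waveform(peak_gi, t_on, lat[["i"]], time),
    description = sprintf("%s-like alpha pair (peak latencies %g/%g ms)",
                          type, lat[["e"]], lat[["i"]]))
}

#' Synthetic voltage-clamp configuration
#'
#' @param holding commanded holding potentials (mV) at the amplifier,
#'   length >= 2; defaults are the -65 / 0 mV pair used in the recordings.
#' @param junction liquid junction potential (mV); the true membrane
#'   potential is \code{holding + junction} (~-10 mV offset).
#' @param reversal_e,reversal_i reversal potentials (mV) of the excitatory
#'   and inhibitory conductances in the forward model; the defaults are the
#'   junction-corrected commanded potentials (-10 and -75 mV), so each
#'   holding potential isolates one conductance as in the recordings.
#' @param noise_sd recording noise s.d. (pA) per time point per sweep.
#' @param n_sweeps sweeps per holding potential (the analysis averages
#'   them, mirroring the 5-10 sweep averaging of the recordings).
#' @param seed integer seed.
#' @return an object of class \code{"clamp_sim_config"}.
#' @export
clamp_sim_config <- function(holding = c(-65, 0), junction = -10,
                             reversal_e = -10, reversal_i = -75,
                             noise_sd = 5, n_sweeps = 5, seed = 1L) {
  errs <- character()
  if (length(holding) < 2) errs <- c(errs, "need >= 2 holding potentials")
  vc <- holding + junction
  if (anyDuplicated(round(vc, 9)))
    errs <- c(errs, "holding potentials after junction correction must be pairwise distinct")
  if (noise_sd < 0) errs <- c(errs, "noise_sd must be >= 0")
  if (n_sweeps < 1) errs <- c(errs, "n_sweeps must be >= 1")
  if (abs(reversal_e - reversal_i) < 1e-9)
    errs <- c(errs, "reversal_e must differ from reversal_i")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(holding = holding, junction = junction,
                 reversal_e = reversal_e, reversal_i = reversal_i,
                 noise_sd = noise_sd, n_sweeps = as.integer(n_sweeps),
                 seed = as.integer(seed)),
            class = "clamp_sim_config")
}

#' Simulate voltage-clamp currents from known conductances
#'
#' Forward model of the recording: at each commanded potential
#' \eqn{V_{cmd}} the true membrane potential is
#' \eqn{V_{corr} = V_{cmd} + junction}, and the clamp current is
#' \deqn{I(t) = g_e(t)(V_{corr} - E_e) + g_i(t)(V_{corr} - E_i) + \epsilon,}
#' with i.i.d. Gaussian noise per sweep.  The emitted traces carry the
#' commanded (uncorrected) potentials, matching the convention that raw
#' recordings are not junction-corrected.
#'
#' @param truth a \code{\link{ground_truth_conductance}}.
#' @param cfg a \code{\link{clamp_sim_config}}.
#' @return a \code{\link{clamp_trace_set}} with per-sweep current matrices.
#' @export
simulate_clamp_currents <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth_conductance"),
            inherits(cfg, "clamp_sim_config"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  nt <- length(truth$time)
  traces <- lapply(cfg$holding, function(v_cmd) {
    v <- v_cmd + cfg$junction
    clean <- truth$ge * (v - cfg$reversal_e) + truth$gi * (v - cfg$reversal_i)
    noise <- if (cfg$noise_sd > 0)
      matrix(stats::rnorm(nt * cfg$n_sweeps, 0, cfg$noise_sd), nt) else
      matrix(0, nt, cfg$n_sweeps)
    clean + noise
  })
  names(traces) <- format(cfg$holding, trim = TRUE)
  clamp_trace_set(truth$time, traces, cfg$holding, cfg$junction)
}

#' Synthetic zone-map configuration
#'
#' @param grid_shape integer (rows, cols) of the stimulation grid; the
#'   standard scan is 10 x 10.
#' @param cell_size subregion size in micrometers as (width, height); the
#'   standard subregion is 100 x 70 um (column spacing 100, row spacing 70).
#' @param profile_center (row, col) grid coordinates of the sensitivity
#'   peak (1-based, fractional allowed); defaults to the grid middle.
#' @param profile_sigma Gaussian width of the spatial profile (grid units).
#' @param peak_amplitude peak EPSC amplitude (pA, > 0); the default is the
#'   reported mean compound center EPSC (120.8 pA).
#' @param noise_sd additive Gaussian noise s.d. (pA) per cell.
#' @param seed integer seed.
#' @return an object of class \code{"zone_map_sim_config"}.
#' @export
zone_map_sim_config <- function(grid_shape = c(10, 10), cell_size = c(100, 70),
                                profile_center = NULL, profile_sigma = 1.5,
                                peak_amplitude = 120.8, noise_sd = 5,
                                seed = 1L) {
  errs <- character()
  if (any(grid_shape < 1)) errs <- c(errs, "grid dimensions must be >= 1")
  if (peak_amplitude <= 0) errs <- c(errs, "peak_amplitude must be > 0")
  if (profile_sigma <= 0) errs <- c(errs, "profile_sigma must be > 0")
  if (noise_sd < 0) errs <- c(errs, "noise_sd must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  if (is.null(profile_center))
    profile_center <- (grid_shape + 1) / 2
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 profile_center = profile_center,
                 profile_sigma = profile_sigma,
                 peak_amplitude = peak_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "zone_map_sim_config")
}

#' Simulate a grid-scan EPSC amplitude map
#'
#' Per-cell peak amplitude \eqn{A \exp(-d^2/2\sigma^2)} plus Gaussian
#' noise, where \eqn{d} is the grid-unit distance of the cell from the
#' profile center; negative values are clipped at zero (amplitudes are
#' magnitudes).
#'
#' @param cfg a \code{\link{zone_map_sim_config}}.
#' @return a \code{\link{zone_map}} whose \code{soma} is the profile center.
#' @export
simulate_zone_map <- function(cfg) {
  stopifnot(inherits(cfg, "zone_map_sim_config"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  rows <- seq_len(cfg$grid_shape[1])
  cols <- seq_len(cfg$grid_shape[2])
  d2 <- outer((rows - cfg$profile_center[1])^2,
              (cols - cfg$profile_center[2])^2, "+")
  amp <- cfg$peak_amplitude * exp(-d2 / (2 * cfg$profile_sigma^2))
  if (cfg$noise_sd > 0)
    amp <- amp + matrix(stats::rnorm(length(amp), 0, cfg$noise_sd),
                        nrow(amp))
  amp <- pmax(amp, 0)
  zone_map(amp, cell_size = cfg$cell_size, soma = cfg$profile_center)
}
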