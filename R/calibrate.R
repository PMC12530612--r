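#' Somatic PSP excursion for a given peak synaptic conductance
#'
#' Simulates a single isolated neuron at rest receiving \code{n_spikes}
#' simultaneous input spikes through one alpha-conductance synapse and
#' returns the peak absolute deviation of the membrane potential from
#' \code{E_L} (no threshold is applied).
#'
#' @param w_nS peak conductance per spike (nS).
#' @param tau synaptic time constant (ms).
#' @param E_rev synaptic reversal potential (mV).
#' @param neuron a \code{\link{neuron_params}}.
#' @param dt integration step (ms).
#' @param n_spikes number of coincident spikes.
#' @param t_max simulated span (ms); defaults to \code{12 * tau} plus the
#'   membrane time constant.
#' @return peak |V - E_L| in mV.
#' @export
psp_peak <- function(w_nS, tau, E_rev, neuron = neuron_params(), dt = 0.1,
                     n_spikes = 1, t_max = NULL) {
  if (is.null(t_max)) t_max <- 12 * tau + neuron$C_m / neuron$g_L
  n_steps <- as.integer(ceiling(t_max / dt))
  tr <- cpp_single_trace(n_steps, dt, neuron$C_m, neuron$g_L, neuron$E_L,
                         neuron$E_L, 0L, w_nS * n_spikes, tau, E_rev)
  max(abs(tr$V - neuron$E_L))
}

#' Calibrate a synaptic weight from PSP amplitude to peak conductance
#'
#' Model weights are stated as PSP amplitudes in mV; the simulator needs
#' peak conductances in nS.  The conversion is found by bisection on the
#' single-neuron simulation: the returned conductance makes one presynaptic
#' spike produce a somatic PSP whose peak equals \code{J_mV} at rest, to a
#' relative tolerance of 0.1%.  Excitatory classes are calibrated against
#' the depolarization peak, inhibitory classes against the magnitude of the
#' hyperpolarization.
#'
#' @param J_mV target PSP amplitude (mV, >= 0).
#' @param tau synaptic time constant (ms).
#' @param E_rev reversal potential (mV) of the synapse.
#' @param neuron a \code{\link{neuron_params}}.
#' @param dt integration step (ms).
#' @param tol relative tolerance on the PSP peak.
#' @param max_iter bisection iteration cap.
#' @return peak conductance in nS.
#' @examples
#' w <- calibrate_weight(1.1, tau = 3, E_rev = 0)
#' psp_peak(w, tau = 3, E_rev = 0)  # ~1.1 mV
#' @export
calibrate_weight <- function(J_mV, tau, E_rev, neuron = neuron_params(),
                             dt = 0.1, tol = 1e-3, max_iter = 200) {
  if (J_mV < 0) stop("J_mV must be >= 0", call. = FALSE)
  if (J_mV == 0) return(0)
  if (abs(E_rev - neuron$E_L) < 1e-9)
    stop("reversal equals resting potential: no PSP can be evoked",
         call. = FALSE)
  f <- function(w) psp_peak(w, tau, E_rev, neuron, dt)
  lo <- 0
  hi <- 1
  it <- 0
  while (f(hi) < J_mV) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) stop("weight calibration failed to bracket the target",
                      call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- f(mid)
    if (abs(p - J_mV) <= tol * J_mV) return(mid)
    if (p < J_mV) lo <- mid else hi <- mid
  }
  stop("weight calibration did not converge within the iteration cap",
       call. = FALSE)
}

#' Calibrate all synapse classes of a model
#'
#' @param syn a \code{\link{synapse_params}} (PSP amplitudes in mV).
#' @param neuron a \code{\link{neuron_params}}.
#' @param dt integration step (ms).
#' @return named numeric vector of peak conductances (nS) for classes
#'   \code{ee, ei, ie, ii, ex, ix} plus \code{retinal} (the stimulus weight,
#'   external excitatory kinetics at \code{J_retinal}).
#' @export
calibrate_weights <- function(syn, neuron = neuron_params(), dt = 0.1) {
  stopifnot(inherits(syn, "synapse_params"))
  exc <- c("ee", "ei", "ex")
  out <- vapply(names(syn$J), function(cl) {
    E_rev <- if (cl %in% exc) syn$E_rev_exc else syn$E_rev_inh
    calibrate_weight(syn$J[[cl]], syn$tau[[cl]], E_rev, neuron, dt)
  }, numeric(1))
  out["retinal"] <- calibrate_weight(syn$J_retinal, syn$tau[["ex"]],
                                     syn$E_rev_exc, neuron, dt)
  out
}
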