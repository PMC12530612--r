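#' Leaky integrate-and-fire neuron parameters
#'
#' All neurons in the network are identical conductance-based
#' leaky integrate-and-fire units: the subthreshold membrane obeys
#' \deqn{C_m \, dV_m/dt = -g_L (V_m - E_L) + \sum_c g_c(t)\,(E_c - V_m),}
#' a spike is emitted when \eqn{V_m} reaches \code{V_th}, after which
#' \eqn{V_m} is reset to \code{E_L} and clamped there for \code{t_ref} ms.
#'
#' @param C_m membrane capacitance (pF).
#' @param g_L leak conductance (nS); the membrane time constant is
#'   \code{C_m / g_L} (15 ms at the defaults).
#' @param E_L leak, reset and initial potential (mV).
#' @param V_th spike threshold (mV); must exceed \code{E_L}.
#' @param t_ref absolute refractory period (ms).
#' @return an object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(C_m = 250, g_L = 50/3, E_L = -70, V_th = -60,
                          t_ref = 3) {
  errs <- character()
  if (!is.numeric(C_m) || length(C_m) != 1 || C_m <= 0)
    errs <- c(errs, "C_m must be a positive scalar (pF)")
  if (!is.numeric(g_L) || length(g_L) != 1 || g_L <= 0)
    errs <- c(errs, "g_L must be a positive scalar (nS)")
  if (!is.numeric(V_th) || !is.numeric(E_L) || V_th <= E_L)
    errs <- c(errs, "V_th must be greater than E_L")
  if (!is.numeric(t_ref) || t_ref < 0)
    errs <- c(errs, "t_ref must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, V_th = V_th, t_ref = t_ref),
            class = "neuron_params")
}

#' Synapse parameters per connection class
#'
#' Synaptic weights are specified the way they are reported for the model:
#' as the peak amplitude \code{J} (mV) of the postsynaptic potential that a
#' single presynaptic spike evokes in a neuron at rest.  The corresponding
#' peak conductances are obtained at run time with
#' \code{\link{calibrate_weights}}.  The six classes are \code{ee}, \code{ei},
#' \code{ie}, \code{ii} (recurrent, pre -> post by population) and \code{ex},
#' \code{ix} (external excitatory / inhibitory drive).  Conductance
#' transients are alpha functions peaking one time constant \code{tau} after
#' arrival, delivered with class delay \code{delay}.
#'
#' @param J named numeric vector of PSP amplitudes (mV), names
#'   \code{ee, ei, ie, ii, ex, ix}; all must be >= 0 (inhibition gets its
#'   sign from the reversal potential, not from \code{J}).
#' @param tau synaptic time constants (ms) per class.
#' @param delay synaptic delays (ms) per class.
#' @param E_rev_exc,E_rev_inh reversal potentials (mV) of the excitatory and
#'   inhibitory transmitter classes.
#' @param J_retinal PSP amplitude (mV) of one retinal input spike; the
#'   stimulus drive to center/surround neurons runs through the external
#'   excitatory class at this calibrated weight.
#' @return an object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(J = c(ee = 0.26, ei = 0.2, ie = 0.4, ii = 0.33,
                                 ex = 0.5, ix = 0.5),
                           tau = c(ee = 3, ei = 3, ie = 5, ii = 5,
                                   ex = 3, ix = 5),
                           delay = c(ee = 1.5, ei = 1.5, ie = 1.5, ii = 1.5,
                                     ex = 1, ix = 1),
                           E_rev_exc = 0, E_rev_inh = -80,
                           J_retinal = 1.1) {
  classes <- c("ee", "ei", "ie", "ii", "ex", "ix")
  J <- .complete_classes(J, classes, "J")
  tau <- .complete_classes(tau, classes, "tau")
  delay <- .complete_classes(delay, classes, "delay")
  errs <- character()
  if (any(J < 0)) errs <- c(errs, "all J must be >= 0 (mV)")
  if (any(tau <= 0)) errs <- c(errs, "all tau must be > 0 (ms)")
  if (any(delay < 0)) errs <- c(errs, "all delay must be >= 0 (ms)")
  if (E_rev_exc <= E_rev_inh)
    errs <- c(errs, "excitatory reversal must exceed inhibitory reversal")
  if (J_retinal < 0) errs <- c(errs, "J_retinal must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(J = J, tau = tau, delay = delay,
                 E_rev_exc = E_rev_exc, E_rev_inh = E_rev_inh,
                 J_retinal = J_retinal),
            class = "synapse_params")
}

.complete_classes <- function(x, classes, what) {
  if (is.null(names(x)) && length(x) == length(classes)) names(x) <- classes
  miss <- setdiff(classes, names(x))
  if (length(miss))
    stop(sprintf("%s is missing classes: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x[classes]
}

#' Distance-dependent connectivity configuration
#'
#' Both populations (6,400 excitatory and 6,400 inhibitory neurons by
#' default) sit on the same \code{grid_side} x \code{grid_side} lattice,
#' folded as a torus to avoid boundary effects.  The probability that a
#' neuron connects to a target at torus distance \eqn{d} is a Gaussian
#' \eqn{p(d) = s \exp(-d^2 / 2\sigma^2)}, with \eqn{\sigma} set by the
#' presynaptic population (\code{sigma_E} for connections made by
#' excitatory neurons, \code{sigma_I} for inhibitory ones, the broader of
#' the two).  The scale \eqn{s} of each class kernel is chosen so that the
#' mean connection probability over the torus equals \code{p[class]},
#' i.e. the expected out-degree is \code{p[class] * grid_side^2}.
#'
#' @param grid_side lattice side length; 80 gives the standard 6,400-neuron
#'   populations.
#' @param sigma_E,sigma_I Gaussian widths (grid points) of connections made
#'   by excitatory and inhibitory neurons.
#' @param p named mean connection probabilities per recurrent class
#'   (\code{ee, ei, ie, ii}); the E-E baseline is 0.135.
#' @param torus logical; periodic boundary (the supported geometry).
#' @return an object of class \code{"connectivity_config"}.
#' @export
connectivity_config <- function(grid_side = 80, sigma_E = 16, sigma_I = 20,
                                p = c(ee = 0.135, ei = 0.135,
                                      ie = 0.135, ii = 0.135),
                                torus = TRUE) {
  classes <- c("ee", "ei", "ie", "ii")
  p <- .complete_classes(p, classes, "p")
  errs <- character()
  if (grid_side < 1 || grid_side != round(grid_side))
    errs <- c(errs, "grid_side must be a positive integer")
  if (sigma_E <= 0 || sigma_I <= 0)
    errs <- c(errs, "sigma_E and sigma_I must be > 0")
  if (any(p < 0 | p > 1))
    errs <- c(errs, "connection probabilities must lie in [0, 1]")
  if (!isTRUE(torus))
    errs <- c(errs, "only the toroidal geometry is supported (torus = TRUE)")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(grid_side = as.integer(grid_side),
                 N_E = as.integer(grid_side^2), N_I = as.integer(grid_side^2),
                 sigma_E = sigma_E, sigma_I = sigma_I, p = p, torus = TRUE),
            class = "connectivity_config")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron: C_m =", x$C_m, "pF, g_L =", signif(x$g_L, 4),
      "nS (tau_m =", signif(x$C_m / x$g_L, 4), "ms), E_L =", x$E_L,
      "mV, V_th =", x$V_th, "mV, t_ref =", x$t_ref, "ms\n")
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Alpha-conductance synapses (J in mV PSP amplitude):\n")
  print(rbind(J_mV = x$J, tau_ms = x$tau, delay_ms = x$delay))
  cat("reversals:", x$E_rev_exc, "mV (exc) /", x$E_rev_inh,
      "mV (inh); retinal J =", x$J_retinal, "mV\n")
  invisible(x)
}

#' @export
print.connectivity_config <- function(x, ...) {
  cat("Toroidal Gaussian connectivity:", x$grid_side, "x", x$grid_side,
      "grid per population, sigma_E =", x$sigma_E, ", sigma_I =", x$sigma_I,
      "\nmean connection probabilities:\n")
  print(x$p)
  invisible(x)
}
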