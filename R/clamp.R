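#' Voltage-clamp trace set
#'
#' Currents recorded (or simulated) at two or more holding potentials,
#' stored against the commanded potentials; sweeps are kept separate until
#' the decomposition averages them.
#'
#' @param time shared time axis (ms).
#' @param traces list of current matrices (pA), one per holding potential,
#'   rows = time points, columns = sweeps (plain vectors are accepted as
#'   single sweeps).
#' @param holding commanded holding potentials (mV), one per trace.
#' @param junction liquid junction potential (mV, default -10).
#' @param corrected logical; whether \code{holding} has already been
#'   junction-corrected.
#' @return an object of class \code{"clamp_trace_set"}.
#' @export
clamp_trace_set <- function(time, traces, holding, junction = -10,
                            corrected = FALSE) {
  traces <- lapply(traces, function(x) {
    x <- as.matrix(x)
    if (nrow(x) != length(time))
      stop("all traces must share the time axis", call. = FALSE)
    x
  })
  if (length(traces) != length(holding))
    stop("one trace matrix per holding potential is required", call. = FALSE)
  vc <- if (corrected) holding else holding + junction
  if (length(unique(round(vc, 9))) < 2)
    stop("need >= 2 distinct corrected holding potentials", call. = FALSE)
  structure(list(time = time, traces = traces, holding = holding,
                 junction = junction, corrected = corrected),
            class = "clamp_trace_set")
}

#' Correct commanded potentials for the liquid junction potential
#'
#' Each commanded potential \eqn{V} becomes \eqn{V + junction}; currents
#' are unchanged.  With the ~-10 mV junction offset the -65/0 mV commanded
#' pair becomes -75/-10 mV.
#'
#' @param cts a \code{\link{clamp_trace_set}}.
#' @return the corrected trace set (idempotent: correcting twice is
#'   refused).
#' @export
correct_junction <- function(cts) {
  stopifnot(inherits(cts, "clamp_trace_set"))
  if (cts$corrected) {
    warning("trace set already junction-corrected; returning unchanged",
            call. = FALSE)
    return(cts)
  }
  cts$holding <- cts$holding + cts$junction
  cts$corrected <- TRUE
  cts
}

#' Decompose clamp currents into excitatory and inhibitory conductances
#'
#' At every time point the currents at the corrected holding potentials
#' \eqn{V_k} are modeled as
#' \eqn{I(V_k) = g_e (V_k - E_e) + g_i (V_k - E_i)} and solved for
#' \eqn{(g_e, g_i)} — exactly for two potentials, by least squares for
#' more.  Sweeps are averaged per potential and a per-trace baseline (mean
#' over \code{baseline_window}) is subtracted first, which makes the
#' estimate invariant to any constant leak current.  Negative estimates
#' (possible under noise) are retained but flagged so that averaging stays
#' unbiased.
#'
#' @param cts a \code{\link{clamp_trace_set}}; junction correction is
#'   applied automatically if it has not been yet.
#' @param reversal_e,reversal_i assumed reversal potentials (mV).
#' @param t_c stimulus onset (ms); anchors the default windows.
#' @param baseline_window (start, stop) ms for baseline subtraction;
#'   defaults to the 50 ms preceding \code{t_c}.  \code{NULL} disables
#'   subtraction when no valid window exists.
#' @param analysis_window (start, stop) ms over which peaks are measured;
#'   defaults to \code{[t_c, t_c + 100]}.
#' @return an object of class \code{"conductance_estimate"}: \code{time},
#'   \code{ge}, \code{gi}, \code{gt} (= ge + gi, nS), peak summaries
#'   \code{peak_ge}, \code{peak_gi}, \code{peak_gt}, time stamps \code{t_c}
#'   (stimulus onset), \code{t_e} (peak excitation), \code{t_T} (peak total
#'   conductance), and a \code{flags} list (\code{negative_ge},
#'   \code{negative_gi}).
#' @export
decompose_conductances <- function(cts, reversal_e = -10, reversal_i = -75,
                                   t_c = 0, baseline_window = NULL,
                                   analysis_window = NULL) {
  stopifnot(inherits(cts, "clamp_trace_set"))
  if (!cts$corrected) cts <- correct_junction(cts)
  if (abs(reversal_e - reversal_i) < 1e-9)
    stop("reversal_e must differ from reversal_i", call. = FALSE)
  V <- cts$holding
  if (length(unique(round(V, 9))) < length(V))
    stop("corrected holding potentials are coincident: singular system",
         call. = FALSE)
  I <- vapply(cts$traces, rowMeans, numeric(length(cts$time)))
  if (is.null(baseline_window) && t_c > min(cts$time))
    baseline_window <- c(max(min(cts$time), t_c - 50), t_c)
  if (!is.null(baseline_window)) {
    sel <- cts$time >= baseline_window[1] & cts$time <= baseline_window[2]
    if (any(sel)) I <- sweep(I, 2, colMeans(I[sel, , drop = FALSE]))
  }
  A <- cbind(V - reversal_e, V - reversal_i)
  if (abs(det(crossprod(A))) < 1e-12)
    stop("holding-potential design is singular", call. = FALSE)
  # g (2 x nt), in nS since I is pA and V is mV
  g <- qr.solve(A, t(I))
  ge <- g[1, ]
  gi <- g[2, ]
  gt <- ge + gi
  if (is.null(analysis_window)) analysis_window <- c(t_c, t_c + 100)
  win <- cts$time >= analysis_window[1] & cts$time <= analysis_window[2]
  if (!any(win)) win <- rep(TRUE, length(cts$time))
  tw <- cts$time[win]
  structure(list(time = cts$time, ge = ge, gi = gi, gt = gt,
                 reversal_e = reversal_e, reversal_i = reversal_i,
                 peak_ge = max(ge[win]), peak_gi = max(gi[win]),
                 peak_gt = max(gt[win]),
                 t_c = t_c, t_e = tw[which.max(ge[win])],
                 t_T = tw[which.max(gt[win])],
                 analysis_window = analysis_window,
                 flags = list(negative_ge = any(ge < -1e-9),
                              negative_gi = any(gi < -1e-9))),
            class = "conductance_estimate")
}

#' Peak latency of a conductance trace
#'
#' Time of the trace maximum relative to \code{t0}; ties are broken by the
#' earliest time.  A flat trace returns a no-peak flag rather than an
#' error.
#'
#' @param trace conductance values.
#' @param time time axis (ms), same length.
#' @param t0 reference time (ms) within the axis.
#' @param flat_tol absolute range below which the trace counts as flat.
#' @return list with \code{latency} (ms, NA when flat), \code{t_peak},
#'   \code{peak}, and logical \code{no_peak}.
#' @export
peak_latency <- function(trace, time, t0, flat_tol = 1e-12) {
  if (!length(trace)) stop("empty trace", call. = FALSE)
  if (length(trace) != length(time))
    stop("trace and time must have equal length", call. = FALSE)
  if (t0 < min(time) || t0 > max(time))
    stop("t0 must lie within the time axis", call. = FALSE)
  if (diff(range(trace)) <= flat_tol)
    return(list(latency = NA_real_, t_peak = NA_real_,
                peak = trace[1], no_peak = TRUE))
  k <- which.max(trace)
  list(latency = time[k] - t0, t_peak = time[k], peak = trace[k],
       no_peak = FALSE)
}

#' Suppression statistics between center-only and center-after-surround
#'
#' Compares peak excitatory (and inhibitory) conductances between the
#' center-only condition (C1) and the center-after-surround condition (Cs),
#' reporting the fractional reduction of peak excitation
#' \eqn{1 - g_e^{Cs}/g_e^{C1}} and its category under the reported rule:
#' strong (> 60%), moderate (20%-60%, boundaries inclusive), mild (< 20%).
#' The surround-evoked inhibitory conductance still present at center onset
#' \eqn{t_c} is reported as well.
#'
#' @param center_only,center_after_surround
#'   \code{\link{decompose_conductances}} results on comparable windows.
#' @param delta_t surround-to-center scheduling delay (ms); 20 ms in the
#'   collision protocol.
#' @return an object of class \code{"suppression_result"} with fields
#'   \code{ge_c1}, \code{ge_cs}, \code{gi_c1}, \code{gi_cs},
#'   \code{reduction_fraction}, \code{category}, \code{gi_at_tc},
#'   \code{delta_t}, \code{undefined} (TRUE when \code{ge_c1 <= 0}).
#' @examples
#' # printed exemplar peaks: 1.7 -> 0.6 nS, reduction 0.647, "strong"
#' @export
suppression_stats <- function(center_only, center_after_surround,
                              delta_t = 20) {
  stopifnot(inherits(center_only, "conductance_estimate"),
            inherits(center_after_surround, "conductance_estimate"))
  ge_c1 <- center_only$peak_ge
  ge_cs <- center_after_surround$peak_ge
  undefined <- ge_c1 <= 0
  reduction <- if (undefined) NA_real_ else 1 - ge_cs / ge_c1
  category <- if (undefined) NA_character_ else
    classify_suppression(reduction)
  k <- which.min(abs(center_after_surround$time - center_after_surround$t_c))
  structure(list(ge_c1 = ge_c1, ge_cs = ge_cs,
                 gi_c1 = center_only$peak_gi,
                 gi_cs = center_after_surround$peak_gi,
                 reduction_fraction = reduction, category = category,
                 gi_at_tc = center_after_surround$gi[k],
                 delta_t = delta_t, undefined = undefined),
            class = "suppression_result")
}

#' Classify a suppression fraction
#'
#' @param reduction fractional reduction of peak center excitation.
#' @return \code{"strong"} (> 0.60), \code{"moderate"} (0.20-0.60,
#'   inclusive) or \code{"mild"} (< 0.20).
#' @export
classify_suppression <- function(reduction) {
  if (is.na(reduction)) return(NA_character_)
  if (reduction > 0.60) "strong"
  else if (reduction >= 0.20) "moderate"
  else "mild"
}

#' Excitation-inhibition trajectory
#'
#' Time-ordered \eqn{(g_e(t), g_i(t))} pairs of an estimate, for
#' trajectory plots of inhibition as a function of excitation.
#'
#' @param estimate a \code{"conductance_estimate"}.
#' @return data.frame with columns \code{time}, \code{ge}, \code{gi}.
#' @export
iso_conductance_trajectory <- function(estimate) {
  stopifnot(inherits(estimate, "conductance_estimate"))
  data.frame(time = estimate$time, ge = estimate$ge, gi = estimate$gi)
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf(
    "peak Ge: %.3g -> %.3g nS; reduction %.1f%% (%s); Gi at t_c: %.3g nS\n",
    x$ge_c1, x$ge_cs, 100 * x$reduction_fraction, x$category, x$gi_at_tc))
  invisible(x)
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf(
    "conductance estimate: peak Ge %.3g nS (t_e = %g ms), peak Gi %.3g nS, peak Gt %.3g nS (t_T = %g ms)\n",
    x$peak_ge, x$t_e, x$peak_gi, x$peak_gt, x$t_T))
  if (x$flags$negative_ge || x$flags$negative_gi)
    cat("  note: negative conductance excursions present (noise)\n")
  invisible(x)
}
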