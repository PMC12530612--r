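#' Trial-averaged conductance trace with quartile band
#'
#' Pointwise mean of the recorded excitatory conductance across trials,
#' with the 25%-75% quartile band used for the shaded traces.
#'
#' @param trials list of \code{"trial_recording"} objects on a common time
#'   axis.
#' @param what which recorded trace to average (\code{"ge"}, \code{"gi"} or
#'   \code{"V"}).
#' @return list with \code{time}, \code{mean}, \code{q25}, \code{q75},
#'   \code{n}.
#' @export
average_trials <- function(trials, what = "ge") {
  if (length(trials) < 2) stop("need >= 2 trials", call. = FALSE)
  t0 <- trials[[1]]$time
  for (tr in trials)
    if (length(tr$time) != length(t0) || any(abs(tr$time - t0) > 1e-9))
      stop("trials do not share a time axis", call. = FALSE)
  m <- vapply(trials, function(tr) tr[[what]], numeric(length(t0)))
  q <- apply(m, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  list(time = t0, mean = rowMeans(m), q25 = q[1, ], q75 = q[2, ],
       n = length(trials))
}

#' Split a center response into monosynaptic and network peaks
#'
#' The center-evoked excitatory conductance is biphasic in the strongly
#' recurrent regime: a low-variance first peak from the direct retinal
#' volley, then a second peak generated by the recurrent network.  The
#' trace maximum over \code{[T_center, T_center + boundary]} is the first
#' (monosynaptic) peak; the maximum over the remaining window is the
#' second (network) peak.  A flat network window is reported with a
#' low-amplitude flag rather than an error.
#'
#' @param trace conductance trace (nS), typically a trial average.
#' @param time time axis (ms).
#' @param T_center center volley onset (ms).
#' @param boundary monosynaptic/network window boundary (ms after
#'   \code{T_center}); defaults to \code{delay_ex + tau_ex + 2} ms, just
#'   past the monosynaptic conductance peak (which, with up to 1 ms of
#'   volley jitter, falls at most \code{delay_ex + tau_ex + 1} ms after
#'   onset) and before the disynaptic network response can contribute.
#' @param syn a \code{\link{synapse_params}} used for the default boundary.
#' @return an object of class \code{"peak_decomposition"}:
#'   \code{first_peak}, \code{first_time}, \code{second_peak},
#'   \code{second_time}, \code{boundary}, \code{baseline},
#'   \code{low_amplitude}.
#' @export
split_peaks <- function(trace, time, T_center, boundary = NULL,
                        syn = synapse_params()) {
  if (is.null(boundary))
    boundary <- syn$delay[["ex"]] + syn$tau[["ex"]] + 2
  if (boundary <= 0) stop("boundary must be > 0 ms", call. = FALSE)
  w1 <- time >= T_center & time <= T_center + boundary
  w2 <- time > T_center + boundary
  if (!any(w1)) stop("first window is empty", call. = FALSE)
  if (!any(w2)) stop("trace must extend beyond the window boundary",
                     call. = FALSE)
  pre <- time < T_center
  baseline <- if (any(pre)) mean(trace[pre]) else 0
  t1 <- time[w1]; t2 <- time[w2]
  k1 <- which.max(trace[w1]); k2 <- which.max(trace[w2])
  first_peak <- trace[w1][k1]
  second_peak <- trace[w2][k2]
  structure(list(first_peak = first_peak, first_time = t1[k1],
                 second_peak = second_peak, second_time = t2[k2],
                 boundary = boundary, baseline = baseline,
                 low_amplitude =
                   (second_peak - baseline) < 0.1 * (first_peak - baseline)),
            class = "peak_decomposition")
}

#' Normalized suppression ratio of the network peak
#'
#' Ratio of the second (network) excitatory-conductance peak with surround
#' co-stimulation to the center-only second peak.  Values below 1 indicate
#' suppression; \code{1 - ratio} is the percent suppression.
#'
#' @param center_with_surround,center_only \code{"peak_decomposition"}
#'   objects from the same recorded neuron and window settings.
#' @return list with \code{ratio}, \code{percent_suppression},
#'   \code{undefined} (TRUE when the center-only network peak is <= 0).
#' @export
suppression_ratio <- function(center_with_surround, center_only) {
  p0 <- center_only$second_peak
  if (p0 <= 0)
    return(list(ratio = NA_real_, percent_suppression = NA_real_,
                undefined = TRUE))
  r <- center_with_surround$second_peak / p0
  list(ratio = r, percent_suppression = 100 * (1 - r), undefined = FALSE)
}

#' Run repeated trials of one condition and summarize the response
#'
#' Runs \code{n_trials} seeded trials of a protocol on a fixed network and
#' recorded neuron, and summarizes the recorded excitatory conductance:
#' trial average with quartile band, monosynaptic/network peak split of the
#' mean trace, per-trial peak values with standard errors, and population
#' rates over the response window.
#'
#' @param network an \code{"sc_network"}.
#' @param weights_nS calibrated peak conductances (nS) incl. \code{retinal}.
#' @param syn,neuron model parameters.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param n_trials number of trials.
#' @param seed master seed; per-trial seeds are derived from it.
#' @param record_neuron global id of the recorded center excitatory neuron.
#' @param dt integration step (ms).
#' @param boundary peak-split boundary (ms), see \code{\link{split_peaks}}.
#' @param keep_trials logical; retain the individual recordings.
#' @return list with \code{average}, \code{peaks}, \code{first_trials},
#'   \code{second_trials}, \code{se_first}, \code{se_second}, \code{rates}
#'   (and \code{trials} when kept).
#' @export
run_condition <- function(network, weights_nS, syn, neuron, protocol,
                          n_trials, seed, record_neuron, dt = 0.1,
                          boundary = NULL, keep_trials = FALSE) {
  seeds <- derive_seeds(seed, paste0(protocol$condition, "_trial", seq_len(n_trials)))
  trials <- lapply(seeds, function(s)
    run_trial(network, weights_nS, syn, neuron, protocol, seed = s,
              record_neuron = record_neuron, dt = dt))
  avg <- average_trials(trials)
  pd <- split_peaks(avg$mean, avg$time, protocol$T_center, boundary, syn)
  per_trial <- vapply(trials, function(tr) {
    p <- split_peaks(tr$ge, tr$time, protocol$T_center, boundary, syn)
    c(p$first_peak, p$second_peak)
  }, numeric(2))
  out <- list(average = avg, peaks = pd,
              first_trials = per_trial[1, ], second_trials = per_trial[2, ],
              se_first = stats::sd(per_trial[1, ]) / sqrt(n_trials),
              se_second = stats::sd(per_trial[2, ]) / sqrt(n_trials),
              rates = population_rates(
                trials, c(protocol$T_center, protocol$T_center + 50)))
  if (keep_trials) out$trials <- trials
  out
}

#' Suppression sweep over recurrent weight grids
#'
#' For every cell of the \code{J_ie} x \code{J_ei} grid (at a fixed E-E
#' level), recalibrates the synaptic weights on the same network topology,
#' runs the center-only and center-during-surround conditions, and stores
#' the normalized center conductance (network-peak ratio with-surround /
#' center-only).  Topology is held fixed across the sweep so colormap
#' differences are attributable to the weights.
#'
#' @param network an \code{"sc_network"}.
#' @param syn base \code{\link{synapse_params}}; \code{J["ee"]} is replaced
#'   by \code{J_ee} and \code{J["ie"]}, \code{J["ei"]} by the grid values.
#' @param neuron a \code{\link{neuron_params}}.
#' @param J_ie_values,J_ei_values weight grids (mV).
#' @param J_ee E-E weight level (mV): 0.13 weak, 0.26 strong.
#' @param n_trials trials per condition per cell (20 in the model
#'   experiments).
#' @param seed master seed.
#' @param protocol_args list of overrides passed to
#'   \code{\link{stimulus_protocol}} for both conditions (e.g. background
#'   rates).
#' @param dt integration step (ms).
#' @return an object of class \code{"sweep_result"}: \code{ratio} and
#'   \code{percent_suppression} matrices (rows = J_ie, cols = J_ei),
#'   \code{se_ratio}, per-cell response rates \code{rate_E}, \code{rate_I},
#'   plus the axes, \code{J_ee} and \code{n_trials}.
#' @export
run_sweep <- function(network, syn, neuron,
                      J_ie_values = c(0.35, 0.40, 0.45),
                      J_ei_values = c(0.15, 0.20, 0.25),
                      J_ee = 0.26, n_trials = 20, seed = 1L,
                      protocol_args = list(), dt = 0.1) {
  if (!length(J_ie_values) || !length(J_ei_values))
    stop("weight grids must be nonempty", call. = FALSE)
  dims <- c(length(J_ie_values), length(J_ei_values))
  ratio <- se_ratio <- pct <- rate_E <- rate_I <- array(NA_real_, dims)
  prot_only <- do.call(stimulus_protocol,
                       c(list(condition = "center_only", T_center = 70,
                              t_stop = 130), protocol_args))
  prot_surr <- do.call(stimulus_protocol,
                       c(list(condition = "center_during_surround",
                              T_center = 70, t_stop = 130), protocol_args))
  record_neuron <- .pick_record_neuron(network, seed, prot_only)
  for (i in seq_along(J_ie_values)) {
    for (j in seq_along(J_ei_values)) {
      syn_ij <- syn
      syn_ij$J[c("ee", "ie", "ei")] <-
        c(J_ee, J_ie_values[i], J_ei_values[j])
      w <- calibrate_weights(syn_ij, neuron, dt)
      cell_seed <- derive_seeds(seed, sprintf("cell_%d_%d", i, j))
      c1 <- run_condition(network, w, syn_ij, neuron, prot_only, n_trials,
                           cell_seed, record_neuron, dt)
      cs <- run_condition(network, w, syn_ij, neuron, prot_surr, n_trials,
                           cell_seed + 1L, record_neuron, dt)
      sr <- suppression_ratio(cs$peaks, c1$peaks)
      ratio[i, j] <- sr$ratio
      pct[i, j] <- sr$percent_suppression
      # delta-method SE of the peak ratio from per-trial network peaks
      if (!sr$undefined)
        se_ratio[i, j] <- abs(sr$ratio) *
          sqrt((cs$se_second / max(cs$peaks$second_peak, 1e-12))^2 +
               (c1$se_second / max(c1$peaks$second_peak, 1e-12))^2)
      rate_E[i, j] <- cs$rates$rate_E
      rate_I[i, j] <- cs$rates$rate_I
    }
  }
  structure(list(J_ie = J_ie_values, J_ei = J_ei_values, J_ee = J_ee,
                 ratio = ratio, percent_suppression = pct,
                 se_ratio = se_ratio, rate_E = rate_E, rate_I = rate_I,
                 n_trials = n_trials, seed = seed,
                 record_neuron = record_neuron),
            class = "sweep_result")
}

.pick_record_neuron <- function(network, seed, protocol) {
  center <- select_center(network$conn$grid_side, protocol$center_radius,
                          protocol$center_count)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  sample(center, 1)
}

#' E-E connection reduction and strength-compensation experiment
#'
#' Reduces the E-E connection probability to the given fractions of its
#' baseline (0.135) while all other classes keep their realized topology
#' and weights, then, at the lowest fraction, scales the strength of the
#' remaining E-E synapses up to \code{max(multipliers)}.  For each setting
#' it reports the second (network) peak of the trial-averaged center-only
#' excitatory conductance as a fraction of the baseline value, the percent
#' elimination \eqn{1 - peak/baseline}, and under strength scaling the
#' percent recovery \eqn{peak/baseline}.
#'
#' @param conn a \code{\link{connectivity_config}} (baseline p_ee).
#' @param syn,neuron model parameters (weights fixed across settings apart
#'   from the E-E scaling).
#' @param probabilities fractions of baseline E-E probability, starting
#'   with 1 (the baseline itself).
#' @param multipliers E-E strength multipliers applied at the smallest
#'   probability fraction (in addition to 1, which is already covered).
#' @param n_trials trials per setting.
#' @param seed master seed.
#' @param protocol_args overrides for \code{\link{stimulus_protocol}}.
#' @param conditions conditions to run per setting; the elimination /
#'   recovery metrics use \code{"center_only"}.
#' @param dt integration step (ms).
#' @return an object of class \code{"ee_reduction_result"}: a data.frame
#'   \code{table} with one row per (setting, condition) holding
#'   \code{p_fraction}, \code{multiplier}, \code{second_peak}, \code{se},
#'   \code{fraction_of_baseline}, \code{elimination_pct},
#'   \code{recovery_pct}, plus the baseline peak.
#' @export
run_ee_reduction <- function(conn, syn, neuron,
                             probabilities = c(1, 0.8, 0.6, 0.4),
                             multipliers = c(1.25, 1.5, 1.75, 2),
                             n_trials = 20, seed = 1L,
                             protocol_args = list(),
                             conditions = "center_only", dt = 0.1) {
  stopifnot(probabilities[1] == 1)
  p_base <- conn$p[["ee"]]
  network <- build_network(conn, seed = derive_seeds(seed, "topology"))
  weights <- calibrate_weights(syn, neuron, dt)
  prots <- lapply(conditions, function(cond)
    do.call(stimulus_protocol,
            c(list(condition = cond, T_center = 100, t_stop = 160),
              protocol_args)))
  record_neuron <- .pick_record_neuron(network, seed, prots[[1]])
  rows <- list()
  base_peak <- NULL
  run_setting <- function(net, w, syn_s, label, p_frac, mult) {
    for (k in seq_along(conditions)) {
      res <- run_condition(net, w, syn_s, neuron, prots[[k]], n_trials,
                            derive_seeds(seed, paste0(label, conditions[k])),
                            record_neuron, dt)
      rows[[length(rows) + 1]] <<- data.frame(
        p_fraction = p_frac, multiplier = mult, condition = conditions[k],
        second_peak = res$peaks$second_peak, se = res$se_second,
        first_peak = res$peaks$first_peak)
      if (conditions[k] == "center_only" && p_frac == 1 && mult == 1)
        base_peak <<- res$peaks$second_peak
    }
  }
  run_setting(network, weights, syn, "baseline", 1, 1)
  net_p <- network
  for (p_frac in probabilities[-1]) {
    net_p <- rebuild_class(network, "ee", p_frac * p_base,
                           seed = derive_seeds(seed, paste0("pee", p_frac)))
    run_setting(net_p, weights, syn, paste0("p", p_frac), p_frac, 1)
  }
  p_min <- min(probabilities)
  for (m in multipliers) {
    syn_m <- syn
    syn_m$J[["ee"]] <- syn$J[["ee"]] * m
    w_m <- weights
    w_m[["ee"]] <- calibrate_weight(syn_m$J[["ee"]], syn$tau[["ee"]],
                                    syn$E_rev_exc, neuron, dt)
    run_setting(net_p, w_m, syn_m, paste0("m", m), p_min, m)
  }
  tab <- do.call(rbind, rows)
  tab$fraction_of_baseline <- tab$second_peak / base_peak
  tab$elimination_pct <- ifelse(
    tab$condition == "center_only" & tab$multiplier == 1,
    100 * (1 - tab$fraction_of_baseline), NA_real_)
  tab$recovery_pct <- ifelse(
    tab$condition == "center_only" & tab$multiplier > 1,
    100 * tab$fraction_of_baseline, NA_real_)
  structure(list(table = tab, baseline_peak = base_peak,
                 p_baseline = p_base, n_trials = n_trials, seed = seed,
                 record_neuron = record_neuron),
            class = "ee_reduction_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "suppression sweep at J_ee = %g mV (%d trials/cell):\npercent suppression (rows J_ie, cols J_ei):\n",
    x$J_ee, x$n_trials))
  m <- round(x$percent_suppression, 1)
  dimnames(m) <- list(paste0("J_ie=", x$J_ie), paste0("J_ei=", x$J_ei))
  print(m)
  invisible(x)
}

#' @export
print.ee_reduction_result <- function(x, ...) {
  cat(sprintf("E-E reduction experiment (baseline p_ee = %g, %d trials):\n",
              x$p_baseline, x$n_trials))
  print(x$table, digits = 3)
  invisible(x)
}
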